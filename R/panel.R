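#' Select a fingerprint SNP panel
#'
#' Filters candidate SNPs down to a cross-platform comparison panel using the
#' five fingerprinting rules: present on at least `min_platform` of the
#' genotyping platforms, bi-allelic with known alleles, minor allele
#' frequency above `min_maf`, at least `min_spacing` bp from any other
#' retained SNP on the same chromosome, and non-complementary alleles (no
#' A/T, no G/C) so that genotypes can be reconciled across unknown DNA strand
#' orientations. Spacing is enforced greedily left-to-right by position.
#'
#' @param candidates Tibble with `marker_id`, `chrom`, `pos`, `allele1`,
#'   `allele2` and optionally `maf`.
#' @param platform_presence Optional named numeric vector mapping marker_id
#'   to the fraction of platforms carrying it; markers absent from the map
#'   are treated as present everywhere.
#' @param freq_source Optional named numeric vector mapping marker_id to
#'   MAF; overrides a `maf` column.
#' @param min_platform Minimum platform fraction (default 0.8).
#' @param min_maf MAF must exceed this (default 0.17). SNPs with unknown MAF
#'   are kept (frequencies may be unavailable).
#' @param min_spacing Minimum bp between retained SNPs on a chromosome
#'   (default 50,000).
#' @return A tibble of retained SNPs sorted by (chrom, pos), of class
#'   `fp_panel`, with attribute `n_dropped` counting exclusions per rule.
#' @examples
#' cand <- tibble::tibble(
#'   marker_id = c("rs1", "rs2", "rs3"), chrom = "1",
#'   pos = c(1e5, 1.2e5, 2e5), allele1 = c("A", "A", "A"),
#'   allele2 = c("G", "T", "C"), maf = c(0.3, 0.4, 0.1))
#' select_panel(cand)  # rs2 is strand-ambiguous, rs3 fails MAF
#' @export
select_panel <- function(candidates, platform_presence = NULL,
                         freq_source = NULL, min_platform = 0.8,
                         min_maf = 0.17, min_spacing = 50000) {
  x <- tibble::as_tibble(candidates)
  stopifnot(all(c("marker_id", "chrom", "pos", "allele1", "allele2")
                %in% names(x)))
  if (!is.null(freq_source)) x$maf <- unname(freq_source[x$marker_id])
  if (!"maf" %in% names(x)) x$maf <- NA_real_

  dropped <- c(platform = 0L, biallelic = 0L, maf = 0L,
               complementary = 0L, spacing = 0L)

  if (!is.null(platform_presence)) {
    pres <- platform_presence[x$marker_id]
    pres[is.na(pres)] <- 1
    keep <- pres >= min_platform
    dropped["platform"] <- sum(!keep)
    x <- x[keep, ]
  }

  valid_allele <- function(a) a %in% c("A", "C", "G", "T")
  keep <- valid_allele(x$allele1) & valid_allele(x$allele2) &
    x$allele1 != x$allele2
  dropped["biallelic"] <- sum(!keep)
  x <- x[keep, ]

  keep <- is.na(x$maf) | x$maf > min_maf
  dropped["maf"] <- sum(!keep)
  x <- x[keep, ]

  keep <- !is_complementary_pair(x$allele1, x$allele2)
  dropped["complementary"] <- sum(!keep)
  x <- x[keep, ]

  x <- dplyr::arrange(x, .data$chrom, .data$pos)
  keep <- unlist(lapply(split(x$pos, x$chrom), function(pos) {
    k <- logical(length(pos))
    last <- -Inf
    for (i in seq_along(pos)) {
      if (pos[i] - last >= min_spacing) {
        k[i] <- TRUE
        last <- pos[i]
      }
    }
    k
  }), use.names = FALSE)
  # split() keeps chromosome groups in the arranged order
  dropped["spacing"] <- sum(!keep)
  x <- x[keep, ]

  if (sum(dropped) > 0)
    message(sum(dropped), " candidate SNP(s) excluded (",
            paste(names(dropped), dropped, sep = "=", collapse = ", "), ")")
  attr(x, "n_dropped") <- dropped
  class(x) <- c("fp_panel", class(x))
  x
}

complement_allele <- function(a) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[a])
}

is_complementary_pair <- function(a1, a2) {
  complement_allele(a1) == a2
}

#' Determine the allele orientation of a dataset SNP against the panel
#'
#' Fingerprint panels contain only non-complementary SNPs, so a dataset's
#' allele pair can always be mapped onto the panel's canonical pair without
#' knowing the DNA strand: `"same"` (pairs match in order), `"swapped"`
#' (match in reverse order), `"flipped"`/`"swapped_flipped"` (match after
#' complementing the dataset alleles), or `"incompatible"`. Downstream
#' encoding uses the orientation to remap genotype codes so that hom-allele1
#' and hom-allele2 always refer to the panel's canonical alleles (swapped
#' orientations exchange codes 0 and 2).
#'
#' @param data_a1,data_a2 Dataset allele pair (single characters).
#' @param panel_a1,panel_a2 Panel canonical allele pair; must not be
#'   complementary.
#' @return One of `"same"`, `"swapped"`, `"flipped"`, `"swapped_flipped"`,
#'   `"incompatible"` (vectorised).
#' @examples
#' harmonize_alleles("T", "C", "A", "G")  # "flipped"
#' @export
harmonize_alleles <- function(data_a1, data_a2, panel_a1, panel_a2) {
  n <- max(length(data_a1), length(panel_a1))
  data_a1 <- rep_len(data_a1, n); data_a2 <- rep_len(data_a2, n)
  panel_a1 <- rep_len(panel_a1, n); panel_a2 <- rep_len(panel_a2, n)
  if (any(is_complementary_pair(panel_a1, panel_a2)))
    stop("panel SNPs must be non-complementary")
  ok <- data_a1 %in% c("A", "C", "G", "T") & data_a2 %in% c("A", "C", "G", "T")
  c1 <- complement_allele(data_a1)
  c2 <- complement_allele(data_a2)
  out <- rep("incompatible", n)
  out[ok & data_a1 == panel_a1 & data_a2 == panel_a2] <- "same"
  out[ok & data_a1 == panel_a2 & data_a2 == panel_a1] <- "swapped"
  idx <- ok & out == "incompatible"
  out[idx & c1 == panel_a1 & c2 == panel_a2] <- "flipped"
  out[idx & c1 == panel_a2 & c2 == panel_a1] <- "swapped_flipped"
  out
}

#' Read or write a fingerprint panel file
#'
#' Panels are exchanged as TSV with header columns `marker_id`, `chrom`,
#' `pos`, `allele1`, `allele2`, `maf`.
#'
#' @param path File path.
#' @param panel Panel tibble (for writing).
#' @return `read_panel()` returns the panel tibble; `write_panel()` returns
#'   `path` invisibly.
#' @export
read_panel <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    marker_id = readr::col_character(), chrom = readr::col_character(),
    pos = readr::col_integer(), allele1 = readr::col_character(),
    allele2 = readr::col_character(), maf = readr::col_double()
  ), progress = FALSE)
  class(x) <- c("fp_panel", class(x))
  x
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  cols <- c("marker_id", "chrom", "pos", "allele1", "allele2", "maf")
  if (!"maf" %in% names(panel)) panel$maf <- NA_real_
  readr::write_tsv(panel[, cols], path, progress = FALSE)
  invisible(path)
}
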
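#' Build bit-packed fingerprints from a genotype dataset
#'
#' Matches the fingerprint panel against a dataset, harmonizes allele
#' orientations, and encodes each sample's genotypes over the panel two bits
#' per SNP into paired 64-bit words (`00` hom allele1, `01` het, `10` hom
#' allele2, `11` missing; trailing pad bits are set to missing). Panel SNPs
#' absent from the dataset, and dataset SNPs whose alleles cannot be mapped
#' onto the panel's canonical alleles (including monomorphic "0" allele
#' columns), are encoded missing.
#'
#' @param data A `plink_data` list from [read_plink()], or any list with
#'   `snps`, `samples` and a `genotypes` matrix (SNPs x samples, codes
#'   0/1/2/NA relative to the dataset's own alleles).
#' @param panel Fingerprint panel tibble ([select_panel()]/[read_panel()]).
#' @param match_by `"rsid"` (marker_id, with position fallback for unmatched
#'   panel SNPs) or `"position"` (chrom+pos only). rsID first by default
#'   because positions vary across genome assemblies.
#' @param min_genotyped Samples with fewer panel SNPs genotyped than this are
#'   flagged (default 1,000).
#' @param dataset_id Optional prefix used to disambiguate sample IDs when
#'   merging multiple datasets.
#' @return An object of class `kin_fp`: list with `sample_id`,
#'   `n_genotyped`, `flagged` (logical, low genotyping), panel size `S`, the
#'   `panel`, and raw word matrices `hi`, `lo` (8 bytes per word, one column
#'   per sample).
#' @export
pack_fingerprints <- function(data, panel, match_by = c("rsid", "position"),
                              min_genotyped = 1000, dataset_id = NULL) {
  match_by <- match.arg(match_by)
  snps <- data$snps
  S <- nrow(panel)
  n <- ncol(data$genotypes)

  # panel row -> dataset row (NA when absent)
  midx <- rep(NA_integer_, S)
  if (match_by == "rsid") {
    midx <- match(panel$marker_id, snps$marker_id)
    unmatched <- is.na(midx)
    if (any(unmatched)) {
      key_p <- paste(panel$chrom[unmatched], panel$pos[unmatched])
      midx[unmatched] <- match(key_p, paste(snps$chrom, snps$pos))
    }
  } else {
    midx <- match(paste(panel$chrom, panel$pos), paste(snps$chrom, snps$pos))
  }

  geno <- matrix(NA_integer_, nrow = S, ncol = n)
  hit <- which(!is.na(midx))
  if (length(hit)) {
    drow <- midx[hit]
    orient <- harmonize_alleles(snps$allele1[drow], snps$allele2[drow],
                                panel$allele1[hit], panel$allele2[hit])
    usable <- orient %in% c("same", "flipped", "swapped", "swapped_flipped")
    g <- data$genotypes[drow[usable], , drop = FALSE]
    swap <- orient[usable] %in% c("swapped", "swapped_flipped")
    if (any(swap)) g[swap, ] <- 2L - g[swap, , drop = FALSE]
    geno[hit[usable], ] <- g
  }

  packed <- cpp_pack(geno)
  ids <- colnames(data$genotypes) %||% data$samples$sample_id
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  if (anyDuplicated(ids)) {
    message("duplicate sample IDs disambiguated with suffixes")
    ids <- make.unique(ids, sep = "#")
  }
  if (!is.null(dataset_id)) ids <- paste0(dataset_id, ":", ids)

  new_kin_fp(ids, packed$hi, packed$lo, packed$n_genotyped, panel,
             min_genotyped)
}

new_kin_fp <- function(ids, hi, lo, n_genotyped, panel, min_genotyped = 1000) {
  structure(list(
    sample_id = ids,
    hi = hi, lo = lo,
    n_genotyped = as.integer(n_genotyped),
    flagged = as.integer(n_genotyped) < min_genotyped,
    S = nrow(panel),
    panel = panel
  ), class = "kin_fp")
}

#' @export
print.kin_fp <- function(x, ...) {
  cat("<kin_fp> ", length(x$sample_id), " samples x ", x$S,
      " fingerprint SNPs (", x$S %/% 64 + (x$S %% 64 > 0),
      " word pairs/sample)\n", sep = "")
  cat("  genotyped SNPs/sample: median ",
      stats::median(x$n_genotyped), ", min ", min(x$n_genotyped),
      "; ", sum(x$flagged), " sample(s) flagged low-genotyped\n", sep = "")
  invisible(x)
}

#' @export
length.kin_fp <- function(x) length(x$sample_id)

#' Subset fingerprints by sample
#'
#' @param x A `kin_fp` object.
#' @param i Sample index or sample_id vector.
#' @param ... Unused.
#' @return A `kin_fp` with the selected samples.
#' @export
`[.kin_fp` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$sample_id)
  stopifnot(!anyNA(i))
  x$sample_id <- x$sample_id[i]
  x$hi <- x$hi[, i, drop = FALSE]
  x$lo <- x$lo[, i, drop = FALSE]
  x$n_genotyped <- x$n_genotyped[i]
  x$flagged <- x$flagged[i]
  x
}

#' Combine fingerprint sets built on the same panel
#'
#' @param ... `kin_fp` objects sharing one panel.
#' @return A combined `kin_fp`.
#' @export
c.kin_fp <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, TRUE, "kin_fp")))
  S <- unique(vapply(parts, `[[`, 1L, "S"))
  stopifnot(length(S) == 1)
  ids <- unlist(lapply(parts, `[[`, "sample_id"))
  if (anyDuplicated(ids)) {
    message("duplicate sample IDs disambiguated with suffixes")
    ids <- make.unique(ids, sep = "#")
  }
  out <- parts[[1]]
  out$sample_id <- ids
  out$hi <- do.call(cbind, lapply(parts, `[[`, "hi"))
  out$lo <- do.call(cbind, lapply(parts, `[[`, "lo"))
  out$n_genotyped <- unlist(lapply(parts, `[[`, "n_genotyped"))
  out$flagged <- unlist(lapply(parts, `[[`, "flagged"))
  out
}

#' Decode packed fingerprints back to genotype codes
#'
#' @param fp A `kin_fp` object.
#' @return Integer matrix (S x n) with codes 0/1/2/NA relative to the
#'   panel's canonical alleles.
#' @export
unpack_fingerprints <- function(fp) {
  stopifnot(inherits(fp, "kin_fp"))
  g <- cpp_unpack(fp$hi, fp$lo, fp$S)
  colnames(g) <- fp$sample_id
  rownames(g) <- fp$panel$marker_id
  g
}

# Flat binary persistence for packed fingerprints.
# Layout (little-endian):
#   bytes 0-7   magic "KINFP\1\0\0"
#   int32       S (panel SNPs)
#   int32       n (samples)
#   int32       W (64-bit words per sample per plane)
#   n x int32   n_genotyped
#   id table    n NUL-terminated sample id strings
#   8*W*n bytes hi words, column-major
#   8*W*n bytes lo words, column-major
# The panel itself is not stored; pair it with write_panel().

#' Persist packed fingerprints as a flat binary file
#'
#' Writes/reads the word arrays with a small self-describing header (magic,
#' panel size, sample count, word count, per-sample genotyped counts, sample
#' id table, then the hi and lo word planes column-major). The panel is not
#' embedded; supply it again on read.
#'
#' @param fp A `kin_fp` object.
#' @param path File path.
#' @param panel Panel tibble to attach on read.
#' @param min_genotyped Flagging threshold applied on read.
#' @return `write_fingerprints()` returns `path` invisibly;
#'   `read_fingerprints()` returns a `kin_fp`.
#' @export
write_fingerprints <- function(fp, path) {
  stopifnot(inherits(fp, "kin_fp"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("KINFP\x01"), con)
  writeBin(as.raw(c(0, 0)), con)
  n <- length(fp$sample_id)
  writeBin(as.integer(c(fp$S, n, nrow(fp$hi) / 8)), con, size = 4,
           endian = "little")
  writeBin(fp$n_genotyped, con, size = 4, endian = "little")
  writeBin(fp$sample_id, con)
  writeBin(as.vector(fp$hi), con)
  writeBin(as.vector(fp$lo), con)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path, panel, min_genotyped = 1000) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8)
  if (!identical(magic[1:6], charToRaw("KINFP\x01")))
    stop("not a kinmatch fingerprint file: ", path)
  hdr <- readBin(con, "integer", 3, size = 4, endian = "little")
  S <- hdr[1]; n <- hdr[2]; W <- hdr[3]
  if (S != nrow(panel))
    stop("panel size mismatch: file has ", S, ", panel has ", nrow(panel))
  ngen <- readBin(con, "integer", n, size = 4, endian = "little")
  ids <- readBin(con, "character", n)
  hi <- matrix(readBin(con, "raw", 8 * W * n), nrow = 8 * W)
  lo <- matrix(readBin(con, "raw", 8 * W * n), nrow = 8 * W)
  new_kin_fp(ids, hi, lo, ngen, panel, min_genotyped)
}
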
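#' Read a PLINK 1.x binary genotype dataset
#'
#' Reads the `.bed`/`.bim`/`.fam` triple into SNP metadata, sample metadata
#' and a genotype matrix. Only the SNP-major binary layout is supported
#' (magic bytes `0x6C 0x1B`, mode byte `0x01`): each SNP occupies
#' `ceiling(n_samples / 4)` bytes, two bits per sample from the low bits of
#' each byte, with codes `00` hom-allele1, `10` het, `11` hom-allele2 and
#' `01` missing.
#'
#' @param prefix Path prefix; `<prefix>.bed`, `<prefix>.bim` and
#'   `<prefix>.fam` must exist. Alternatively pass explicit paths.
#' @param bed,bim,fam Explicit file paths (override `prefix`).
#' @return A list of class `plink_data` with elements
#'   * `snps`: tibble with `marker_id`, `chrom`, `pos`, `allele1`, `allele2`
#'     (allele1 is the PLINK A1/minor allele),
#'   * `samples`: tibble with `family_id`, `sample_id`, `father_id`,
#'     `mother_id`, `sex` (`"male"`, `"female"`, `"unknown"`),
#'   * `genotypes`: integer matrix (SNPs x samples) with codes 0 (hom
#'     allele1), 1 (het), 2 (hom allele2), `NA` (missing).
#' @seealso [write_plink()]
#' @export
read_plink <- function(prefix = NULL, bed = NULL, bim = NULL, fam = NULL) {
  if (!is.null(prefix)) {
    bed <- bed %||% paste0(prefix, ".bed")
    bim <- bim %||% paste0(prefix, ".bim")
    fam <- fam %||% paste0(prefix, ".fam")
  }
  stopifnot(!is.null(bed), !is.null(bim), !is.null(fam))

  bim_tbl <- readr::read_table(
    bim,
    col_names = c("chrom", "marker_id", "cm", "pos", "allele1", "allele2"),
    col_types = readr::cols(
      chrom = readr::col_character(), marker_id = readr::col_character(),
      cm = readr::col_double(), pos = readr::col_integer(),
      allele1 = readr::col_character(), allele2 = readr::col_character()
    ),
    progress = FALSE
  )
  fam_tbl <- readr::read_table(
    fam,
    col_names = c("family_id", "sample_id", "father_id", "mother_id",
                  "sex", "phenotype"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  fam_tbl$sex <- unname(c("1" = "male", "2" = "female")[fam_tbl$sex])
  fam_tbl$sex[is.na(fam_tbl$sex)] <- "unknown"
  fam_tbl$father_id[fam_tbl$father_id == "0"] <- NA_character_
  fam_tbl$mother_id[fam_tbl$mother_id == "0"] <- NA_character_
  fam_tbl$phenotype <- NULL

  n_snps <- nrow(bim_tbl)
  n_samples <- nrow(fam_tbl)
  bytes_per_snp <- ceiling(n_samples / 4)
  expected_len <- 3 + as.double(bytes_per_snp) * n_snps

  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic bytes): ", bed)
  if (raw[3] != as.raw(0x01))
    stop("unsupported .bed mode byte (only SNP-major 0x01 is supported): ",
         bed)
  if (length(raw) != expected_len)
    stop(sprintf(
      "truncated or oversized .bed: %d bytes, expected %d for %d SNPs x %d samples",
      length(raw), expected_len, n_snps, n_samples))

  geno <- decode_bed_body(raw[-(1:3)], n_snps, n_samples)
  rownames(geno) <- bim_tbl$marker_id
  colnames(geno) <- fam_tbl$sample_id
  structure(list(snps = bim_tbl[, c("marker_id", "chrom", "pos",
                                    "allele1", "allele2")],
                 samples = fam_tbl, genotypes = geno),
            class = "plink_data")
}

# Lookup-table decode of the .bed payload; PLINK 2-bit codes to 0/1/2/NA.
decode_bed_body <- function(body, n_snps, n_samples) {
  bytes_per_snp <- ceiling(n_samples / 4)
  # 256 x 4 table: genotype of samples 1..4 within each byte value
  two_bits <- function(v, k) bitwAnd(bitwShiftR(v, 2 * (k - 1)), 3L)
  code_map <- c(0L, NA_integer_, 1L, 2L)  # 00, 01, 10, 11
  lut <- vapply(1:4, function(k) code_map[two_bits(0:255, k) + 1L],
                integer(256))
  idx <- as.integer(body) + 1L
  full <- matrix(0L, nrow = 4 * bytes_per_snp, ncol = n_snps)
  dim(idx) <- c(bytes_per_snp, n_snps)
  for (k in 1:4) full[seq(k, by = 4, length.out = bytes_per_snp), ] <-
    lut[idx, k]
  t(full)[, seq_len(n_samples), drop = FALSE]
}

#' Write a PLINK 1.x binary genotype dataset
#'
#' Inverse of [read_plink()]; writes SNP-major `.bed`/`.bim`/`.fam` files.
#'
#' @param snps Tibble with `marker_id`, `chrom`, `pos`, `allele1`, `allele2`.
#' @param samples Tibble with `family_id`, `sample_id`, `father_id`,
#'   `mother_id`, `sex`.
#' @param genotypes Integer matrix (SNPs x samples), codes 0/1/2/NA.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(snps, samples, genotypes, prefix) {
  stopifnot(nrow(snps) == nrow(genotypes),
            nrow(samples) == ncol(genotypes))
  n_snps <- nrow(snps)
  n_samples <- nrow(samples)

  bim <- data.frame(chrom = snps$chrom, marker_id = snps$marker_id, cm = 0,
                    pos = snps$pos, allele1 = snps$allele1,
                    allele2 = snps$allele2)
  readr::write_tsv(bim, paste0(prefix, ".bim"), col_names = FALSE,
                   progress = FALSE)

  sex_code <- c(male = "1", female = "2", unknown = "0")[samples$sex]
  sex_code[is.na(sex_code)] <- "0"
  fam <- data.frame(family_id = samples$family_id,
                    sample_id = samples$sample_id,
                    father_id = ifelse(is.na(samples$father_id), "0",
                                       samples$father_id),
                    mother_id = ifelse(is.na(samples$mother_id), "0",
                                       samples$mother_id),
                    sex = sex_code, phenotype = "-9")
  readr::write_tsv(fam, paste0(prefix, ".fam"), col_names = FALSE,
                   progress = FALSE)

  bytes_per_snp <- ceiling(n_samples / 4)
  # map 0/1/2/NA to PLINK 2-bit codes 00/10/11/01
  codes <- c(`0` = 0L, `1` = 2L, `2` = 3L)
  g <- t(genotypes)  # samples x snps
  m <- matrix(1L, nrow = 4 * bytes_per_snp, ncol = n_snps)
  m[seq_len(n_samples), ] <- ifelse(is.na(g), 1L, codes[as.character(g)])
  byte_val <- m[seq(1, 4 * bytes_per_snp, by = 4), , drop = FALSE] +
    4L * m[seq(2, 4 * bytes_per_snp, by = 4), , drop = FALSE] +
    16L * m[seq(3, 4 * bytes_per_snp, by = 4), , drop = FALSE] +
    64L * m[seq(4, 4 * bytes_per_snp, by = 4), , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(byte_val)), con)
  invisible(prefix)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
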
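#' Pairwise mismatch statistics for one sample pair
#'
#' Compares two bit-packed fingerprints over the panel and returns the
#' mismatch counts and rates:
#' * `n_compared`: SNPs genotyped in both samples,
#' * `n_mismatch`: compared SNPs with unequal genotypes (IBS `I < 2`),
#' * `n_both_hom`: compared SNPs with two homozygous genotypes,
#' * `n_DO` / `n_SO`: different / same homozygotes among those,
#' * `agmr = n_mismatch / n_compared` (all genotype mismatch rate),
#' * `hgmr = n_DO / (n_DO + n_SO)` (homozygous genotype mismatch rate),
#'   `NA` when no SNP has two homozygous genotypes,
#' * `comparable`: `FALSE` when `n_compared < min_compared`.
#'
#' @param fp A `kin_fp` fingerprint set.
#' @param a,b Sample indices or sample IDs within `fp` (`b` may live in
#'   `fp_b` when comparing across sets built on the same panel).
#' @param fp_b Optional second fingerprint set for `b`.
#' @param min_compared Pairs with fewer jointly genotyped SNPs are flagged
#'   incomparable (default 64).
#' @return A one-row tibble (class `kin_pairs`).
#' @examples
#' sim <- simulate_cohort(sim_config(S = 256, n_unrelated = 2, seed = 1))
#' pair_stats(sim$fingerprints, 1, 2)
#' @export
pair_stats <- function(fp, a, b, fp_b = NULL, min_compared = 64) {
  stopifnot(inherits(fp, "kin_fp"))
  if (is.character(a)) a <- match(a, fp$sample_id)
  if (is.null(fp_b)) {
    if (is.character(b)) b <- match(b, fp$sample_id)
    stopifnot(!is.na(a), !is.na(b), a != b)
    cnt <- cpp_pair_counts(fp$hi, fp$lo, a - 1L, b - 1L)
    ids <- fp$sample_id[c(a, b)]
  } else {
    stopifnot(inherits(fp_b, "kin_fp"), fp$S == fp_b$S)
    if (is.character(b)) b <- match(b, fp_b$sample_id)
    both <- c.kin_fp(fp[a], fp_b[b])
    cnt <- cpp_pair_counts(both$hi, both$lo, 0L, 1L)
    ids <- c(fp$sample_id[a], fp_b$sample_id[b])
  }
  pairs_tbl(ids[1], ids[2], cnt, min_compared)
}

pairs_tbl <- function(id_a, id_b, counts, min_compared) {
  out <- tibble::tibble(
    id_a = id_a,
    id_b = id_b,
    n_compared = as.integer(counts[, 1]),
    n_mismatch = as.integer(counts[, 2]),
    n_both_hom = as.integer(counts[, 3]),
    n_DO = as.integer(counts[, 4])
  )
  out$n_SO <- out$n_both_hom - out$n_DO
  out$agmr <- ifelse(out$n_compared > 0, out$n_mismatch / out$n_compared,
                     NA_real_)
  out$hgmr <- ifelse(out$n_both_hom > 0, out$n_DO / out$n_both_hom,
                     NA_real_)
  out$comparable <- out$n_compared >= min_compared
  class(out) <- c("kin_pairs", class(out))
  out
}

#' Mismatch statistics for all sample pairs
#'
#' Runs the bitwise comparison kernel over every unordered sample pair and
#' returns one row per pair (the driver behind the naive duplicate scan).
#' Memory grows as `n(n-1)/2` rows; for duplicate detection at scale use
#' [naive_scan()] and friends, which only return matching pairs.
#'
#' @inheritParams pair_stats
#' @return A tibble of pair statistics (class `kin_pairs`), `n(n-1)/2` rows.
#' @export
all_pairs_stats <- function(fp, min_compared = 64) {
  stopifnot(inherits(fp, "kin_fp"), length(fp) >= 2)
  cnt <- cpp_all_pair_counts(fp$hi, fp$lo)
  pairs_tbl(fp$sample_id[cnt[, 1]], fp$sample_id[cnt[, 2]],
            cnt[, 3:6, drop = FALSE], min_compared)
}

#' Mismatch statistics for an explicit list of pairs
#'
#' @inheritParams pair_stats
#' @param pairs Tibble or data frame with columns `id_a`, `id_b` (sample IDs
#'   in `fp`).
#' @return A tibble of pair statistics (class `kin_pairs`).
#' @export
pairs_stats <- function(fp, pairs, min_compared = 64) {
  stopifnot(inherits(fp, "kin_fp"))
  i <- match(pairs$id_a, fp$sample_id)
  j <- match(pairs$id_b, fp$sample_id)
  if (anyNA(i) || anyNA(j))
    stop("pair sample IDs not found in fingerprint set")
  cnt <- cpp_pair_counts(fp$hi, fp$lo, i - 1L, j - 1L)
  pairs_tbl(pairs$id_a, pairs$id_b, cnt, min_compared)
}

#' Write pair statistics as TSV
#'
#' Columns `id_a, id_b, n_compared, n_mismatch, n_both_hom, n_DO, agmr,
#' hgmr`, rates with six decimals.
#'
#' @param pairs A `kin_pairs` tibble.
#' @param path Output path.
#' @export
write_pairs_tsv <- function(pairs, path) {
  out <- pairs[, c("id_a", "id_b", "n_compared", "n_mismatch",
                   "n_both_hom", "n_DO")]
  out$agmr <- sprintf("%.6f", pairs$agmr)
  out$hgmr <- ifelse(is.na(pairs$hgmr), "NA", sprintf("%.6f", pairs$hgmr))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
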
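#' Duplicate (identical-pair) scanners
#'
#' Three algorithms to find identical sample pairs (same subject or MZ twin)
#' among bit-packed fingerprints:
#'
#' * `naive_scan()` compares every pair over the full panel (`O(n^2 S)`);
#'   it is exhaustive and serves as the reference for the other two.
#' * `quadratic_scan()` screens each pair on the first `m` jointly genotyped
#'   SNPs (accumulated in 64-SNP blocks) and abandons it once `k` mismatches
#'   are seen; survivors are verified over the full panel, so its reported
#'   set is a subset of the naive set with no false positives (`O(n^2)`).
#'   Missed-pair rates follow the binomial tail of [quadratic_fn_rate()].
#' * `subquadratic_scan()` repeatedly draws `m` low-missingness SNPs, codes
#'   each sample's genotypes at them into one integer key, sorts the keys,
#'   and takes equal adjacent keys as putative duplicates; putative pairs
#'   are verified over the full panel, and the loop stops after `c_rounds`
#'   consecutive rounds without a new confirmed pair (`O(n log n)` per
#'   round). Per-round sensitivity follows [subquadratic_sensitivity()]; it
#'   is intended for datasets with low genotype missing rates.
#'
#' All three report pairs with full-panel AGMR below `agmr_cutoff` and at
#' least `min_compared` jointly genotyped SNPs.
#'
#' @param fp A `kin_fp` fingerprint set.
#' @param agmr_cutoff Report pairs with AGMR below this (default 0.20).
#' @param min_compared Minimum jointly genotyped SNPs (default 64).
#' @param m SNPs screened per pair (quadratic, default 64) or per round
#'   (sub-quadratic, default 20).
#' @param k Mismatch threshold of the quadratic screen (default 8).
#' @param c_rounds Convergence: stop after this many consecutive rounds
#'   without a new confirmed pair (default 10).
#' @param max_rounds Hard cap on rounds (default 1000).
#' @param pool_quantile SNPs with missing rate at or below this quantile
#'   form the sampling pool of the sub-quadratic scan (default 0.2, at
#'   least `10 * m` SNPs).
#' @param seed Random seed for the sub-quadratic scan (default 0).
#' @return A `kin_pairs` tibble of identical pairs with a `detected_by`
#'   column; the sub-quadratic result also carries attributes `n_rounds`
#'   and `round_found` (round index per confirmed pair).
#' @examples
#' sim <- simulate_cohort(sim_config(S = 512, n_unrelated = 20,
#'                                   n_duplicates = 3, seed = 7))
#' naive_scan(sim$fingerprints)
#' @export
naive_scan <- function(fp, agmr_cutoff = 0.20, min_compared = 64) {
  stopifnot(inherits(fp, "kin_fp"), length(fp) >= 2)
  hits <- cpp_naive_scan(fp$hi, fp$lo, agmr_cutoff, min_compared)
  out <- pairs_tbl(fp$sample_id[hits[, 1]], fp$sample_id[hits[, 2]],
                   hits[, 3:6, drop = FALSE], min_compared)
  out$detected_by <- rep("naive", nrow(out))
  out
}

#' @rdname naive_scan
#' @export
quadratic_scan <- function(fp, m = 64, k = 8, agmr_cutoff = 0.20,
                           min_compared = 64) {
  stopifnot(inherits(fp, "kin_fp"), length(fp) >= 2, k >= 1, m >= 1)
  cand <- cpp_quadratic_screen(fp$hi, fp$lo, m, k)
  verify_pairs(fp, cand[, 1], cand[, 2], agmr_cutoff, min_compared,
               "quadratic")
}

verify_pairs <- function(fp, i, j, agmr_cutoff, min_compared, label) {
  if (length(i) == 0) {
    out <- pairs_tbl(character(), character(),
                     matrix(numeric(), ncol = 4), min_compared)
    out$detected_by <- character()
    return(out)
  }
  cnt <- cpp_pair_counts(fp$hi, fp$lo, i - 1L, j - 1L)
  out <- pairs_tbl(fp$sample_id[i], fp$sample_id[j],
                   cnt, min_compared)
  keep <- out$comparable & !is.na(out$agmr) & out$agmr < agmr_cutoff
  out <- out[keep, ]
  out$detected_by <- rep(label, nrow(out))
  out
}

#' @rdname naive_scan
#' @export
subquadratic_scan <- function(fp, m = 20, c_rounds = 10, seed = 0,
                              agmr_cutoff = 0.20, min_compared = 64,
                              pool_quantile = 0.2, max_rounds = 1000) {
  stopifnot(inherits(fp, "kin_fp"), length(fp) >= 2)
  set.seed(seed)
  pool <- subquad_pool(fp, m, pool_quantile)
  n <- length(fp)

  confirmed <- new.env(parent = emptyenv())
  putative <- new.env(parent = emptyenv())
  rows <- list()
  round_found <- integer()
  idle <- 0L
  rounds <- 0L
  while (idle < c_rounds && rounds < max_rounds) {
    rounds <- rounds + 1L
    hit <- subquad_round(fp, pool, m)
    new_pairs <- NULL
    if (nrow(hit)) {
      key <- paste(hit[, 1], hit[, 2])
      fresh <- !vapply(key, exists, TRUE, envir = putative)
      for (kk in key[fresh]) assign(kk, TRUE, envir = putative)
      new_pairs <- hit[fresh, , drop = FALSE]
    }
    found_new <- FALSE
    if (!is.null(new_pairs) && nrow(new_pairs)) {
      ver <- verify_pairs(fp, new_pairs[, 1], new_pairs[, 2],
                          agmr_cutoff, min_compared, "subquadratic")
      if (nrow(ver)) {
        rows[[length(rows) + 1]] <- ver
        round_found <- c(round_found, rep(rounds, nrow(ver)))
        found_new <- TRUE
      }
    }
    idle <- if (found_new) 0L else idle + 1L
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    verify_pairs(fp, integer(), integer(), agmr_cutoff, min_compared,
                 "subquadratic")
  attr(out, "n_rounds") <- rounds
  attr(out, "round_found") <- round_found
  out
}

# SNP pool for key-building: lowest-missing-rate SNPs (ties included),
# at least 10*m of them.
subquad_pool <- function(fp, m, pool_quantile) {
  miss <- cpp_missing_counts(fp$hi, fp$lo, fp$S)
  cut <- stats::quantile(miss, pool_quantile, type = 1)
  pool <- which(miss <= cut)
  if (length(pool) < min(10 * m, fp$S)) {
    ord <- order(miss)
    pool <- ord[seq_len(min(10 * m, fp$S))]
  }
  pool
}

# One sort round: draw m SNPs, build keys, return matrix of adjacent-equal
# (putative identical) index pairs. Samples missing any drawn genotype get a
# sentinel key and are excluded from matching this round. Equal-key runs
# longer than 2 yield all within-run pairs.
subquad_round <- function(fp, pool, m) {
  snps <- sample(pool, m, replace = FALSE)
  key <- cpp_sort_keys(fp$hi, fp$lo, snps - 1L)
  ok <- which(!is.na(key))
  ord <- ok[order(key[ok])]
  k <- key[ord]
  runs <- rle(k)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  long <- which(runs$lengths >= 2)
  if (!length(long)) return(matrix(integer(), ncol = 2))
  pairs <- lapply(long, function(r) {
    idx <- ord[starts[r]:ends[r]]
    t(utils::combn(sort(idx), 2))
  })
  do.call(rbind, pairs)
}

#' Per-round putative matches of the sub-quadratic scan
#'
#' Diagnostic/calibration helper: runs `n_rounds` independent sort rounds
#' (no convergence rule, no verification) and reports every adjacent-equal
#' key match per round. Useful for measuring per-round sensitivity against
#' [subquadratic_sensitivity()].
#'
#' @inheritParams naive_scan
#' @param n_rounds Number of rounds to run.
#' @return A tibble with `round`, `id_a`, `id_b`.
#' @export
subquad_rounds <- function(fp, m = 20, n_rounds = 10, seed = 0,
                           pool_quantile = 0.2) {
  stopifnot(inherits(fp, "kin_fp"))
  set.seed(seed)
  pool <- subquad_pool(fp, m, pool_quantile)
  out <- lapply(seq_len(n_rounds), function(r) {
    hit <- subquad_round(fp, pool, m)
    if (!nrow(hit)) return(NULL)
    tibble::tibble(round = r, id_a = fp$sample_id[hit[, 1]],
                   id_b = fp$sample_id[hit[, 2]])
  })
  dplyr::bind_rows(out)
}
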
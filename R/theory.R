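#' Allele-frequency model for expectation formulas
#'
#' The closed-form expectations for the mismatch-rate statistics average over
#' the allele frequencies of the panel SNPs. Two models are supported: allele
#' frequencies uniformly distributed over an interval (the default, 0.1--0.9),
#' or an explicit vector of per-SNP frequencies.
#'
#' @param kind `"uniform_interval"` or `"explicit"`.
#' @param lo,hi Interval bounds for the uniform model; `0 < lo < hi < 1`.
#' @param freqs Numeric vector of per-SNP allele frequencies in (0,1) for the
#'   explicit model.
#' @return An object of class `freq_spec`.
#' @examples
#' freq_spec()                       # uniform on (0.1, 0.9)
#' freq_spec("explicit", freqs = c(0.2, 0.5, 0.4))
#' @export
freq_spec <- function(kind = c("uniform_interval", "explicit"),
                      lo = 0.1, hi = 0.9, freqs = NULL) {
  kind <- match.arg(kind)
  if (kind == "uniform_interval") {
    stopifnot(is.numeric(lo), is.numeric(hi), lo > 0, hi < 1, lo < hi)
  } else {
    stopifnot(is.numeric(freqs), length(freqs) > 0,
              all(freqs > 0), all(freqs < 1))
  }
  structure(list(kind = kind, lo = lo, hi = hi, freqs = freqs),
            class = "freq_spec")
}

# E[f(p)] under a freq_spec. All integrands used in this package are
# polynomials in p of degree <= 4, so a 16-node Gauss-Legendre rule on
# (lo, hi) is exact for the uniform model (exact through degree 31).
freq_expect <- function(freq, f) {
  stopifnot(inherits(freq, "freq_spec"))
  if (freq$kind == "explicit") return(mean(f(freq$freqs)))
  nodes <- gauss_legendre_16(freq$lo, freq$hi)
  sum(nodes$w * f(nodes$x)) / (freq$hi - freq$lo)
}

# 16-node Gauss-Legendre rule mapped to (a, b). Abscissae/weights on (-1, 1)
# from standard tables (Abramowitz & Stegun 25.4.30).
gauss_legendre_16 <- function(a, b) {
  x <- c(0.0950125098376374, 0.2816035507792589, 0.4580167776572274,
         0.6178762444026438, 0.7554044083550030, 0.8656312023878318,
         0.9445750230732326, 0.9894009349916499)
  w <- c(0.1894506104550685, 0.1826034150449236, 0.1691565193950025,
         0.1495959888165767, 0.1246289712555339, 0.0951585116824928,
         0.0622535239386479, 0.0271524594117541)
  xs <- c(-rev(x), x)
  ws <- c(rev(w), w)
  list(x = (b - a) / 2 * xs + (a + b) / 2, w = (b - a) / 2 * ws)
}

#' IBD sharing profiles of the standard relationship classes
#'
#' Probabilities `P(Z = 0, 1, 2)` of sharing 0, 1 or 2 alleles identical by
#' descent at a locus, for each relationship class, assuming no inbreeding:
#' identical pairs (same subject or MZ twins), parent-offspring, full
#' siblings, second-degree relatives (grandparent-grandchild, avuncular, half
#' sibling), third-degree relatives (first cousin, half-avuncular), and
#' unrelated pairs.
#'
#' @return A tibble with columns `relationship`, `p0`, `p1`, `p2`.
#' @examples
#' ibd_profiles()
#' @export
ibd_profiles <- function() {
  tibble::tibble(
    relationship = c("ID", "PO", "FS", "D2", "D3", "UN"),
    p0 = c(0, 0, 1 / 4, 1 / 2, 3 / 4, 1),
    p1 = c(0, 1, 1 / 2, 1 / 2, 1 / 4, 0),
    p2 = c(1, 0, 1 / 4, 0, 0, 0)
  )
}

ibd_profile <- function(relationship) {
  pr <- ibd_profiles()
  row <- pr[pr$relationship == relationship, ]
  if (nrow(row) != 1) stop("unknown relationship: ", relationship)
  c(p0 = row$p0, p1 = row$p1, p2 = row$p2)
}

check_profile <- function(profile) {
  profile <- as.numeric(profile)
  stopifnot(length(profile) == 3, all(profile >= 0), all(profile <= 1),
            abs(sum(profile) - 1) < 1e-9)
  profile
}

#' Conditional IBS distribution given IBD state
#'
#' For a bi-allelic SNP with allele frequency `p` in a random-mating
#' population in Hardy-Weinberg equilibrium, returns the 3x3 table of
#' probabilities `P(I | Z)` that a pair of individuals shows `I` alleles
#' identical by state given that they share `Z` alleles identical by descent.
#'
#' @param p Allele frequency in (0, 1).
#' @return A 3x3 numeric matrix; rows are `I = 0, 1, 2`, columns `Z = 0, 1,
#'   2`. Each column sums to 1.
#' @examples
#' p_ibs_given_ibd(0.5)
#' @export
p_ibs_given_ibd <- function(p) {
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p >= 1)
    stop("`p` must be a single allele frequency in (0, 1)")
  q <- 1 - p
  m <- matrix(
    c(2 * p^2 * q^2, 4 * p^3 * q + 4 * p * q^3, p^4 + q^4 + 4 * p^2 * q^2,
      0, 2 * p^2 * q + 2 * p * q^2, p^3 + q^3 + p^2 * q + p * q^2,
      0, 0, 1),
    nrow = 3,
    dimnames = list(I = 0:2, Z = 0:2)
  )
  m
}

#' Expected all-genotype mismatch rate (AGMR) for a relationship
#'
#' The AGMR of a sample pair is the fraction of jointly genotyped SNPs with
#' IBS state `I < 2`. Its expectation for a relationship with IBD profile
#' `(p0, p1, p2)` is the profile-weighted average of the conditional mismatch
#' probabilities `P(I < 2 | Z)`, averaged over the allele-frequency model.
#'
#' @param profile Either a relationship label (`"ID"`, `"PO"`, `"FS"`,
#'   `"D2"`, `"D3"`, `"UN"`) or a numeric vector `(p0, p1, p2)`.
#' @param freq A [freq_spec()].
#' @return Expected AGMR as a fraction.
#' @examples
#' expected_agmr("UN")   # about 0.54
#' expected_agmr("PO")   # about 0.39
#' @export
expected_agmr <- function(profile, freq = freq_spec()) {
  if (is.character(profile)) profile <- ibd_profile(profile)
  profile <- check_profile(profile)
  mis1 <- 1 - freq_expect(freq, function(p) {
    q <- 1 - p
    p^3 + q^3 + p^2 * q + p * q^2
  })
  mis0 <- 1 - freq_expect(freq, function(p) {
    q <- 1 - p
    p^4 + q^4 + 4 * p^2 * q^2
  })
  profile[1] * mis0 + profile[2] * mis1
}

# Per-SNP expected probabilities of different/same homozygotes for a profile.
hgmr_components <- function(profile, freq) {
  e_do <- profile[1] * freq_expect(freq, function(p) 2 * p^2 * (1 - p)^2)
  e_so <- profile[1] * freq_expect(freq, function(p) p^4 + (1 - p)^4) +
    profile[2] * freq_expect(freq, function(p) p^3 + (1 - p)^3) +
    profile[3] * freq_expect(freq, function(p) p^2 + (1 - p)^2)
  list(do = e_do, so = e_so)
}

#' Expected homozygous genotype mismatch rate (HGMR) for a relationship
#'
#' The HGMR of a sample pair counts only SNPs at which both samples are
#' homozygous, and reports the fraction showing different homozygotes
#' (AA|BB). Its expectation is `E[P(DO)] / E[P(DO) + P(SO)]` where, at a SNP
#' with allele frequency p, `P(DO) = P(Z=0) 2p^2q^2` and
#' `P(SO) = P(Z=0)(p^4+q^4) + P(Z=1)(p^3+q^3) + P(Z=2)(p^2+q^2)`.
#'
#' @inheritParams expected_agmr
#' @return Expected HGMR as a fraction. Exactly 0 for parent-offspring and
#'   identical pairs.
#' @examples
#' expected_hgmr("FS")   # about 0.0454
#' expected_hgmr("UN")   # about 0.2172
#' @export
expected_hgmr <- function(profile, freq = freq_spec()) {
  if (is.character(profile)) profile <- ibd_profile(profile)
  profile <- check_profile(profile)
  cmp <- hgmr_components(profile, freq)
  if (cmp$do + cmp$so == 0) return(0)
  cmp$do / (cmp$do + cmp$so)
}

#' Predicted standard deviation of HGMR
#'
#' With a panel of `S` independent SNPs, the count of different-homozygote
#' sites is approximately binomial and dominates the variability of HGMR, so
#' `SD(HGMR) ~ sqrt(P_DO (1 - P_DO) / S) / E[P(DO) + P(SO)]` with `P_DO` the
#' per-SNP probability of different homozygotes.
#'
#' @inheritParams expected_agmr
#' @param S Panel size (number of SNPs), default 10,000.
#' @return Predicted SD of HGMR as a fraction.
#' @examples
#' sd_hgmr("FS")   # about 0.0031 at S = 10,000
#' @export
sd_hgmr <- function(profile, freq = freq_spec(), S = 10000) {
  if (is.character(profile)) profile <- ibd_profile(profile)
  profile <- check_profile(profile)
  stopifnot(S >= 1)
  cmp <- hgmr_components(profile, freq)
  if (cmp$do + cmp$so == 0) return(0)
  sqrt(cmp$do * (1 - cmp$do) / S) / (cmp$do + cmp$so)
}

#' Error rates of the early-termination (quadratic) duplicate screen
#'
#' The quadratic duplicate scanner compares `m` jointly genotyped SNPs per
#' pair and abandons the pair once `k` mismatches are seen. For a true
#' identical pair with per-genotype mismatch rate `epsilon` (genotyping
#' error), the false-negative rate is the upper binomial tail
#' `P(X >= k), X ~ Binomial(m, epsilon)`. For an unrelated pair with
#' per-SNP mismatch probability `eta` (about 0.54 for the default
#' allele-frequency model), the false-positive rate of the screen is the
#' lower tail `P(X < k)`; screen survivors are verified over the full panel,
#' so reported duplicates carry no false positives.
#'
#' @param m Number of non-missing SNP comparisons per pair (default 64).
#' @param k Mismatch threshold (default 8).
#' @param epsilon Per-genotype mismatch rate of a true identical pair.
#' @param eta Per-SNP mismatch probability of an unrelated pair.
#' @return A probability.
#' @examples
#' quadratic_fn_rate(epsilon = 0.0548)  # about 0.023
#' quadratic_fp_rate(eta = 0.54)        # < 1e-8
#' @export
quadratic_fn_rate <- function(m = 64, k = 8, epsilon) {
  stopifnot(k >= 0, k <= m, all(epsilon >= 0), all(epsilon <= 1))
  pbinom(k - 1, m, epsilon, lower.tail = FALSE)
}

#' @rdname quadratic_fn_rate
#' @export
quadratic_fp_rate <- function(m = 64, k = 8, eta) {
  stopifnot(k >= 0, k <= m, all(eta >= 0), all(eta <= 1))
  if (k == 0) return(rep(0, length(eta)))
  pbinom(k - 1, m, eta)
}

#' Sensitivity of the sort-based (sub-quadratic) duplicate scan
#'
#' Each round of the sub-quadratic scan detects an identical pair only when
#' all `m` randomly selected SNPs are non-missing and concordant in both
#' samples. With per-SNP missing-or-mismatch rate `delta`, the per-round
#' sensitivity is approximately `exp(-m * delta)` (Poisson approximation) and
#' the false-negative rate after `r` independent rounds is
#' `(1 - exp(-m * delta))^r`.
#'
#' @param m SNPs checked per round (default 20).
#' @param delta Per-SNP missing-or-mismatch rate for the pair.
#' @param r Number of rounds.
#' @return A list with `per_round` sensitivity and `fn_after_r`.
#' @examples
#' subquadratic_sensitivity(m = 20, delta = 0.01, r = 10)
#' @export
subquadratic_sensitivity <- function(m = 20, delta, r = 1) {
  stopifnot(all(delta >= 0), r >= 1)
  per_round <- exp(-m * delta)
  list(per_round = per_round, fn_after_r = (1 - per_round)^r)
}

#' Kinship coefficient from an IBD profile
#'
#' `phi = P(Z = 2)/2 + P(Z = 1)/4`: the probability that one allele sampled
#' from each individual at a locus is identical by descent.
#'
#' @inheritParams expected_agmr
#' @return Kinship coefficient.
#' @examples
#' kinship_from_ibd("ID")  # 0.5
#' kinship_from_ibd("FS")  # 0.25
#' @export
kinship_from_ibd <- function(profile) {
  if (is.character(profile)) profile <- ibd_profile(profile)
  profile <- check_profile(profile)
  profile[3] / 2 + profile[2] / 4
}

#' Binormal separation statistic and AUC
#'
#' For two normally distributed statistics (e.g. the HGMR of full siblings
#' vs. second-degree relatives), the separation is
#' `delta = (mu_x - mu_y) / sqrt(sd_x^2 + sd_y^2)` and the area under the ROC
#' curve is `Phi(delta)`. The variances add under the radical (binormal AUC);
#' a difference there could be negative and is dimensionally unstable.
#'
#' @param mu_x,sd_x Mean and SD of the first statistic.
#' @param mu_y,sd_y Mean and SD of the second statistic.
#' @return A list with `delta` and `auc`.
#' @examples
#' separation_delta(0.104, 0.005, 0.0454, 0.0031)
#' @export
separation_delta <- function(mu_x, sd_x, mu_y, sd_y) {
  stopifnot(sd_x > 0, sd_y > 0)
  delta <- (mu_x - mu_y) / sqrt(sd_x^2 + sd_y^2)
  list(delta = delta, auc = pnorm(delta))
}

#' Moment estimate of P(Z = 0) from the observed IBS-0 rate
#'
#' Documented helper for the classical method-of-moments identity
#' `P(Z=0) = P(I=0) / P(I=0 | Z=0)`. Replacing the expected IBS-0 rate by the
#' observed rate can yield values above 1, which is why the classifier in
#' this package works directly on mismatch rates instead; this helper is not
#' part of the decision path.
#'
#' @param ibs0_rate Observed fraction of compared SNPs with IBS state 0.
#' @param freq A [freq_spec()].
#' @return Estimate of `P(Z = 0)` (not truncated).
#' @export
p_z0_from_ibs <- function(ibs0_rate, freq = freq_spec()) {
  denom <- freq_expect(freq, function(p) 2 * p^2 * (1 - p)^2)
  ibs0_rate / denom
}

#' Expectation table for all relationship classes
#'
#' Convenience table collecting, per relationship: the IBD profile, kinship
#' coefficient, expected AGMR, expected HGMR and its predicted SD at panel
#' size `S`.
#'
#' @inheritParams sd_hgmr
#' @param freq A [freq_spec()].
#' @return A tibble with one row per relationship.
#' @examples
#' expectation_table()
#' @export
expectation_table <- function(freq = freq_spec(), S = 10000) {
  pr <- ibd_profiles()
  dplyr::mutate(
    pr,
    kinship = purrr::pmap_dbl(list(.data$p0, .data$p1, .data$p2),
                              function(a, b, c) kinship_from_ibd(c(a, b, c))),
    expected_agmr = purrr::pmap_dbl(
      list(.data$p0, .data$p1, .data$p2),
      function(a, b, c) expected_agmr(c(a, b, c), freq)),
    expected_hgmr = purrr::pmap_dbl(
      list(.data$p0, .data$p1, .data$p2),
      function(a, b, c) expected_hgmr(c(a, b, c), freq)),
    sd_hgmr = purrr::pmap_dbl(
      list(.data$p0, .data$p1, .data$p2),
      function(a, b, c) sd_hgmr(c(a, b, c), freq, S))
  )
}
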
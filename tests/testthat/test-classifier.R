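# Bayes relationship classifier over joint (HGMR, AGMR).

make_stats <- function(x, y) {
  tibble::tibble(id_a = "a", id_b = "b", n_compared = 10000L,
                 n_mismatch = as.integer(round(y * 10000)),
                 n_both_hom = 3000L, n_DO = as.integer(round(x * 3000)),
                 n_SO = 3000L - as.integer(round(x * 3000)),
                 agmr = y, hgmr = x, comparable = TRUE)
}

test_that("bivariate density has the right peak and integrates to one", {
  m <- default_model()
  p <- m$params[m$params$relationship == "FS", ]
  # uncorrelated normal peaks at 1/(2 pi sx sy)
  m0 <- m
  m0$params$rho[m0$params$relationship == "FS"] <- 0
  expect_equal(rel_density(m0, "FS", p$mu_hgmr, p$mu_agmr),
               1 / (2 * pi * p$sd_hgmr * p$sd_agmr))
  # each density integrates to 1 over the plane (trapezoid grid)
  for (r in c("FS", "D2", "D3", "PO")) {
    pp <- m$params[m$params$relationship == r, ]
    xs <- if (r == "PO") seq(0, 0.01, length.out = 1201)[-1] - 0.01 / 2400 else
      seq(pp$mu_hgmr - 8 * pp$sd_hgmr, pp$mu_hgmr + 8 * pp$sd_hgmr,
          length.out = 801)
    ys <- seq(pp$mu_agmr - 8 * pp$sd_agmr, pp$mu_agmr + 8 * pp$sd_agmr,
              length.out = 801)
    g <- expand.grid(x = xs, y = ys)
    total <- sum(rel_density(m, r, g$x, g$y)) * diff(xs)[1] * diff(ys)[1]
    expect_equal(total, 1, tolerance = 1e-3)
  }
  # PO density decreases monotonically in HGMR at fixed AGMR
  po <- rel_density(m, "PO", seq(0, 0.01, length.out = 50), 0.3948)
  expect_true(all(diff(po) < 0))
})

test_that("classification stages: identical, unrelated, posterior argmax", {
  m <- default_model()
  expect_equal(as.character(classify_pairs(make_stats(0, 0.001),
                                           m)$relationship), "ID")
  expect_equal(as.character(classify_pairs(make_stats(0.21, 0.54),
                                           m)$relationship), "UN")
  # at the class means the posterior concentrates on that class
  cases <- list(FS = c(0.0486, 0.3359), D2 = c(0.1116, 0.4730),
                D3 = c(0.1732, 0.5107), PO = c(0.0004, 0.3948))
  for (r in names(cases)) {
    got <- classify_pairs(make_stats(cases[[r]][1], cases[[r]][2]), m)
    expect_equal(as.character(got$relationship), r)
    expect_gt(got[[paste0("post_", r)]], 0.99)
  }
  # posteriors sum to one in stage 3
  got <- classify_pairs(make_stats(0.08, 0.40), m)
  expect_equal(got$post_PO + got$post_FS + got$post_D2 + got$post_D3, 1)
})

test_that("undefined HGMR cannot be classified as related", {
  st <- make_stats(NA_real_, 0.45)
  st$n_both_hom <- 0L; st$n_DO <- 0L; st$n_SO <- 0L
  expect_warning(got <- classify_pairs(st), "undefined HGMR")
  expect_equal(as.character(got$relationship), "UN")
  expect_true(is.na(got$post_FS))
})

test_that("scaling all priors leaves labels unchanged", {
  m1 <- default_model(priors = c(PO = 1, FS = 1, D2 = 1, D3 = 1))
  m2 <- default_model(priors = c(PO = 2, FS = 2, D2 = 2, D3 = 2))
  set.seed(10)
  xs <- runif(50, 0, 0.19)
  ys <- runif(50, 0.3, 0.55)
  for (i in seq_along(xs)) {
    s <- make_stats(xs[i], ys[i])
    expect_equal(classify_pairs(s, m1)$relationship,
                 classify_pairs(s, m2)$relationship)
  }
})

test_that("fit_model recovers parameters from simulated pairs", {
  set.seed(20)
  m <- default_model()
  n <- 1000
  sim_rel <- function(r) {
    p <- m$params[m$params$relationship == r, ]
    if (r == "PO") {
      x <- stats::rexp(n, p$k_rate)
      y <- rnorm(n, p$mu_agmr, p$sd_agmr)
    } else {
      z1 <- rnorm(n); z2 <- rnorm(n)
      x <- p$mu_hgmr + p$sd_hgmr * z1
      y <- p$mu_agmr + p$sd_agmr * (p$rho * z1 + sqrt(1 - p$rho^2) * z2)
    }
    tibble::tibble(id_a = "a", id_b = "b", agmr = y, hgmr = x,
                   relationship = r)
  }
  pairs <- dplyr::bind_rows(lapply(c("PO", "FS", "D2", "D3"), sim_rel))
  fit <- fit_model(pairs, m)
  for (r in c("FS", "D2", "D3")) {
    want <- m$params[m$params$relationship == r, ]
    got <- fit$params[fit$params$relationship == r, ]
    expect_lt(abs(got$mu_hgmr - want$mu_hgmr),
              3 * want$sd_hgmr / sqrt(n))
    expect_lt(abs(got$mu_agmr - want$mu_agmr),
              3 * want$sd_agmr / sqrt(n))
    expect_lt(abs(got$rho - want$rho),
              3 * (1 - want$rho^2) / sqrt(n))
  }
  po <- fit$params[fit$params$relationship == "PO", ]
  k <- m$params$k_rate[m$params$relationship == "PO"]
  expect_lt(abs(po$k_rate / k - 1), 0.1)  # 3 SE of 1/mean is ~0.095 k
})

test_that("fit_model degenerate and partial inputs", {
  m <- default_model()
  # single relationship provided: only that entry updated
  fs <- tibble::tibble(agmr = rnorm(100, 0.33, 0.02),
                       hgmr = rnorm(100, 0.05, 0.005),
                       relationship = "FS")
  fit <- fit_model(fs, m)
  expect_equal(fit$params[fit$params$relationship == "D2", ],
               m$params[m$params$relationship == "D2", ])
  expect_false(isTRUE(all.equal(
    fit$params$mu_hgmr[fit$params$relationship == "FS"],
    m$params$mu_hgmr[m$params$relationship == "FS"])))
  # all-zero PO HGMR: exponential rate capped, not infinite
  po <- tibble::tibble(agmr = rnorm(100, 0.39, 0.01), hgmr = 0,
                       relationship = "PO")
  fit2 <- fit_model(po, m)
  expect_equal(fit2$params$k_rate[fit2$params$relationship == "PO"], 1e5)
  # no labelled pairs at all: defaults returned with a warning
  expect_warning(fit3 <- fit_model(fs[0, ], m), "no labelled")
  expect_equal(fit3$params, m$params)
})

test_that("decision boundaries sit where adjacent posteriors are equal", {
  m <- default_model()
  bl <- decision_boundaries(m, n = 151)
  expect_true(all(c("PO/FS", "FS/D2", "D2/D3") %in% bl$boundary))
  cl <- classify_pairs(
    tibble::tibble(id_a = "a", id_b = "b", n_compared = 10000L,
                   n_mismatch = 1L, n_both_hom = 1000L, n_DO = 1L,
                   n_SO = 999L, agmr = bl$agmr, hgmr = bl$hgmr,
                   comparable = TRUE), m)
  check <- which(bl$boundary == "FS/D2" &
                   bl$hgmr < m$hgmr_unrelated_cutoff & !is.na(cl$post_FS))
  expect_gt(length(check), 10)
  for (r in check) {
    expect_lt(abs(cl$post_FS[r] - cl$post_D2[r]), 0.05)
  }
  # symmetric isotropic classes: boundary is the perpendicular bisector
  params <- tibble::tribble(
    ~relationship, ~mu_hgmr, ~sd_hgmr, ~mu_agmr, ~sd_agmr, ~rho, ~k_rate,
    "PO", 0.0004, 0.0007, 0.3948, 0.0147, 0, 2500,
    "FS", 0.05, 0.01, 0.40, 0.01, 0, NA,
    "D2", 0.09, 0.01, 0.40, 0.01, 0, NA,
    "D3", 0.17, 0.01, 0.51, 0.01, 0, NA)
  ms <- relationship_model(params)
  bls <- decision_boundaries(ms, xlim = c(0.05, 0.09), ylim = c(0.38, 0.42),
                             n = 101)
  mid <- bls[bls$boundary == "FS/D2", ]
  expect_true(all(abs(mid$hgmr - 0.07) < 1e-6))
})

test_that("relationship model round-trips through TSV", {
  dir <- withr::local_tempdir()
  m <- default_model()
  path <- file.path(dir, "model.tsv")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(back$params, m$params)
  expect_equal(back$agmr_identical_cutoff, m$agmr_identical_cutoff)
  expect_equal(back$hgmr_unrelated_cutoff, m$hgmr_unrelated_cutoff,
               tolerance = 1e-6)
  expect_equal(tidy(m), m$params)
  expect_equal(glance(m)$n_relationships, 4)
})
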
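#' Relationship model for the Bayes classifier
#'
#' Holds the per-relationship distribution parameters of the joint
#' (HGMR, AGMR) statistics used to classify non-identical close pairs:
#' full-sibling, second- and third-degree pairs follow a bivariate normal
#' with correlation `rho`; parent-offspring pairs use an exponential density
#' `k exp(-k x)` for HGMR (their homozygous mismatches come only from
#' genotyping error) times an independent normal for AGMR.
#'
#' `default_model()` carries the empirical parameters estimated from a large
#' reference collection of reported relative pairs (values stored as
#' fractions; commonly printed as percentages):
#'
#' | relationship | mean HGMR | SD | mean AGMR | SD | rho |
#' |---|---|---|---|---|---|
#' | PO | 0.0004 | (exponential, k = 2500) | 0.3948 | 0.0147 | 0 |
#' | FS | 0.0486 | 0.0102 | 0.3359 | 0.0232 | 0.784 |
#' | D2 | 0.1116 | 0.0135 | 0.4730 | 0.0110 | 0.803 |
#' | D3 | 0.1732 | 0.0135 | 0.5107 | 0.0096 | 0.830 |
#'
#' Identical pairs are excluded upstream by an AGMR cutoff (default 0.20)
#' and unrelated/remote pairs by an HGMR cutoff; the default HGMR cutoff is
#' the midpoint of the analytic third-degree and unrelated expectations
#' (about 0.188) under the uniform(0.1, 0.9) frequency model.
#'
#' @param params Tibble with columns `relationship` (`PO`,`FS`,`D2`,`D3`),
#'   `mu_hgmr`, `sd_hgmr`, `mu_agmr`, `sd_agmr`, `rho`, `k_rate` (k_rate
#'   only used for PO).
#' @param agmr_identical_cutoff Pairs below this AGMR are identical
#'   (default 0.20).
#' @param hgmr_unrelated_cutoff Pairs above this HGMR are unrelated/remote.
#' @param priors Named prior probabilities over `PO`,`FS`,`D2`,`D3`
#'   (default equal).
#' @return An object of class `kin_relmodel`.
#' @examples
#' default_model()
#' @export
relationship_model <- function(params,
                               agmr_identical_cutoff = 0.20,
                               hgmr_unrelated_cutoff = NULL,
                               priors = NULL) {
  stopifnot(all(c("relationship", "mu_hgmr", "sd_hgmr", "mu_agmr",
                  "sd_agmr", "rho", "k_rate") %in% names(params)),
            setequal(params$relationship, c("PO", "FS", "D2", "D3")))
  stopifnot(all(params$sd_agmr > 0), all(abs(params$rho) < 1))
  if (is.null(hgmr_unrelated_cutoff))
    hgmr_unrelated_cutoff <-
      (expected_hgmr("D3") + expected_hgmr("UN")) / 2
  if (is.null(priors))
    priors <- setNames(rep(1 / 4, 4), c("PO", "FS", "D2", "D3"))
  priors <- priors / sum(priors)
  structure(list(params = tibble::as_tibble(params),
                 agmr_identical_cutoff = agmr_identical_cutoff,
                 hgmr_unrelated_cutoff = hgmr_unrelated_cutoff,
                 priors = priors),
            class = "kin_relmodel")
}

# Exponential-rate cap for degenerate all-zero parent-offspring HGMR fits.
K_RATE_MAX <- 1e5

#' @rdname relationship_model
#' @export
default_model <- function(agmr_identical_cutoff = 0.20,
                          hgmr_unrelated_cutoff = NULL, priors = NULL) {
  params <- tibble::tribble(
    ~relationship, ~mu_hgmr, ~sd_hgmr, ~mu_agmr, ~sd_agmr, ~rho, ~k_rate,
    "PO", 0.0004, 0.0007, 0.3948, 0.0147, 0,     2500,
    "FS", 0.0486, 0.0102, 0.3359, 0.0232, 0.784, NA,
    "D2", 0.1116, 0.0135, 0.4730, 0.0110, 0.803, NA,
    "D3", 0.1732, 0.0135, 0.5107, 0.0096, 0.830, NA
  )
  relationship_model(params, agmr_identical_cutoff, hgmr_unrelated_cutoff,
                     priors)
}

#' @export
print.kin_relmodel <- function(x, ...) {
  cat("<kin_relmodel> cutoffs: AGMR(identical) <",
      format(x$agmr_identical_cutoff),
      ", HGMR(unrelated) >", format(round(x$hgmr_unrelated_cutoff, 4)), "\n")
  print(x$params)
  invisible(x)
}

#' @export
tidy.kin_relmodel <- function(x, ...) x$params

#' @export
glance.kin_relmodel <- function(x, ...) {
  tibble::tibble(agmr_identical_cutoff = x$agmr_identical_cutoff,
                 hgmr_unrelated_cutoff = x$hgmr_unrelated_cutoff,
                 n_relationships = nrow(x$params))
}

#' Joint (HGMR, AGMR) density under a relationship
#'
#' Evaluates the model density of observing HGMR `x` and AGMR `y` for a pair
#' with the given relationship: a correlated bivariate normal for FS/D2/D3,
#' or `k exp(-k x) * Normal(y; mu, sd)` for PO.
#'
#' @param model A `kin_relmodel`.
#' @param relationship One of `"PO"`, `"FS"`, `"D2"`, `"D3"`.
#' @param x HGMR value(s) (fraction).
#' @param y AGMR value(s) (fraction).
#' @return Density value(s).
#' @export
rel_density <- function(model, relationship, x, y) {
  stopifnot(inherits(model, "kin_relmodel"))
  if (any(is.na(x))) stop("undefined HGMR: density not available")
  p <- model$params[model$params$relationship == relationship, ]
  if (nrow(p) != 1) stop("unknown relationship: ", relationship)
  exp(rel_log_density(p, relationship, x, y))
}

# log density, safe against underflow in far tails
rel_log_density <- function(p, relationship, x, y) {
  if (relationship == "PO") {
    k <- p$k_rate
    ifelse(x < 0, -Inf, log(k) - k * x) +
      dnorm(y, p$mu_agmr, p$sd_agmr, log = TRUE)
  } else {
    zx <- (x - p$mu_hgmr) / p$sd_hgmr
    zy <- (y - p$mu_agmr) / p$sd_agmr
    rho <- p$rho
    -(zx^2 - 2 * rho * zx * zy + zy^2) / (2 * (1 - rho^2)) -
      log(2 * pi * p$sd_hgmr * p$sd_agmr * sqrt(1 - rho^2))
  }
}

#' Classify sample pairs from their mismatch statistics
#'
#' Three-stage rule applied to each pair:
#' 1. AGMR below the identical cutoff: label `ID`.
#' 2. HGMR above the unrelated cutoff (or undefined): label `UN`, with a
#'    warning for undefined HGMR (close relatedness cannot be assessed).
#' 3. Otherwise the posterior `P(R | x, y)` over `{PO, FS, D2, D3}` is
#'    computed from the model densities and priors; the label is the
#'    maximum-posterior relationship (posterior ties go to the closer
#'    relationship).
#'
#' @param pairs A `kin_pairs` tibble ([all_pairs_stats()], [pairs_stats()]).
#' @param model A `kin_relmodel` (default [default_model()]).
#' @return `pairs` with added columns `relationship` (factor
#'   `ID`,`PO`,`FS`,`D2`,`D3`,`UN`) and posterior columns `post_PO`,
#'   `post_FS`, `post_D2`, `post_D3` (`NA` outside stage 3).
#' @examples
#' stats <- tibble::tibble(id_a = "s1", id_b = "s2", n_compared = 10000L,
#'   n_mismatch = 3359L, n_both_hom = 3000L, n_DO = 146L, n_SO = 2854L,
#'   agmr = 0.3359, hgmr = 0.0486, comparable = TRUE)
#' classify_pairs(stats)  # full sibling
#' @export
classify_pairs <- function(pairs, model = default_model()) {
  stopifnot(inherits(model, "kin_relmodel"))
  n <- nrow(pairs)
  rels <- c("PO", "FS", "D2", "D3")
  post <- matrix(NA_real_, n, 4, dimnames = list(NULL, rels))
  label <- rep("UN", n)

  x <- pairs$hgmr
  y <- pairs$agmr
  is_id <- !is.na(y) & y < model$agmr_identical_cutoff
  label[is_id] <- "ID"
  undef <- !is_id & is.na(x)
  if (any(undef))
    warning(sum(undef), " pair(s) with undefined HGMR labelled UN")
  stage3 <- !is_id & !undef & x <= model$hgmr_unrelated_cutoff
  if (any(stage3)) {
    dens <- vapply(rels, function(r)
      model$priors[[r]] * rel_density(model, r, x[stage3], y[stage3]),
      numeric(sum(stage3)))
    dens <- matrix(dens, ncol = 4, dimnames = list(NULL, rels))
    tot <- rowSums(dens)
    ok <- tot > 0
    post[stage3, ] <- dens / tot
    # argmax with ties to the closer relationship (column order PO..D3)
    pick <- apply(dens, 1, which.max)
    lab <- rels[pick]
    lab[!ok] <- "UN"  # all densities underflowed: too far from every class
    label[stage3] <- lab
    post[which(stage3)[!ok], ] <- NA_real_
  }
  pairs$relationship <- rel_factor(label)
  pairs$post_PO <- unname(post[, "PO"])
  pairs$post_FS <- unname(post[, "FS"])
  pairs$post_D2 <- unname(post[, "D2"])
  pairs$post_D3 <- unname(post[, "D3"])
  pairs
}

#' Fit relationship-model parameters from labelled pairs
#'
#' Re-estimates the distribution parameters from pair statistics with known
#' relationships (e.g. reported pedigree pairs): for FS/D2/D3 the sample
#' means, SDs and Pearson correlation of (HGMR, AGMR); for PO the AGMR
#' normal parameters plus the exponential rate `k = 1 / mean(HGMR)` (moment
#' estimate, capped at `1e5` when all PO HGMRs are zero). Relationships with
#' fewer than `min_pairs` labelled pairs keep the parameters of `base`.
#'
#' @param pairs A `kin_pairs` tibble with a `relationship` column holding
#'   labels among `PO`, `FS`, `D2`, `D3`.
#' @param base Model supplying defaults (default [default_model()]).
#' @param min_pairs Minimum labelled pairs per relationship (default 30).
#' @return A `kin_relmodel`.
#' @export
fit_model <- function(pairs, base = default_model(), min_pairs = 30) {
  stopifnot("relationship" %in% names(pairs))
  params <- base$params
  labelled <- pairs[!is.na(pairs$hgmr) &
                      pairs$relationship %in% params$relationship, ]
  if (nrow(labelled) == 0) {
    warning("no labelled pairs; returning base model unchanged")
    return(base)
  }
  for (r in params$relationship) {
    sub <- labelled[labelled$relationship == r, ]
    if (nrow(sub) < min_pairs) next
    i <- which(params$relationship == r)
    params$mu_agmr[i] <- mean(sub$agmr)
    params$sd_agmr[i] <- sd(sub$agmr)
    params$mu_hgmr[i] <- mean(sub$hgmr)
    params$sd_hgmr[i] <- sd(sub$hgmr)
    if (r == "PO") {
      params$rho[i] <- 0
      params$k_rate[i] <- if (mean(sub$hgmr) > 0)
        min(1 / mean(sub$hgmr), K_RATE_MAX) else K_RATE_MAX
    } else {
      params$rho[i] <- max(min(cor(sub$hgmr, sub$agmr), 0.99), -0.99)
    }
  }
  relationship_model(params, base$agmr_identical_cutoff,
                     base$hgmr_unrelated_cutoff, base$priors)
}

#' Decision boundaries between adjacent relationship classes
#'
#' Evaluates the prior-weighted model densities on an (HGMR, AGMR) grid and
#' extracts, for each adjacent relationship pair (PO/FS, FS/D2, D2/D3), the
#' contour along which the two posteriors are equal. Used for report plots.
#'
#' @param model A `kin_relmodel`.
#' @param xlim,ylim Grid ranges for HGMR and AGMR (fractions).
#' @param n Grid resolution per axis (default 201).
#' @return A tibble with `boundary` (e.g. `"FS/D2"`), `piece` (contour
#'   segment id), `hgmr`, `agmr`.
#' @export
decision_boundaries <- function(model, xlim = c(0, 0.25),
                                ylim = c(0.25, 0.60), n = 201) {
  stopifnot(inherits(model, "kin_relmodel"))
  xs <- seq(xlim[1], xlim[2], length.out = n)
  ys <- seq(ylim[1], ylim[2], length.out = n)
  grid <- expand.grid(x = xs, y = ys)
  ldens <- function(r) {
    p <- model$params[model$params$relationship == r, ]
    d <- log(model$priors[[r]]) + rel_log_density(p, r, grid$x, grid$y)
    matrix(d, nrow = n)
  }
  adj <- list(c("PO", "FS"), c("FS", "D2"), c("D2", "D3"))
  out <- lapply(adj, function(pr) {
    z <- ldens(pr[1]) - ldens(pr[2])
    cl <- grDevices::contourLines(xs, ys, z, levels = 0)
    if (!length(cl)) return(NULL)
    dplyr::bind_rows(lapply(seq_along(cl), function(i)
      tibble::tibble(boundary = paste(pr, collapse = "/"), piece = i,
                     hgmr = cl[[i]]$x, agmr = cl[[i]]$y)))
  })
  dplyr::bind_rows(out)
}

#' Read or write a relationship model as TSV
#'
#' Columns `relationship, mu_hgmr, sd_hgmr, mu_agmr, sd_agmr, rho, k_rate`
#' (fractions), plus a header comment carrying the two cutoffs.
#'
#' @param model A `kin_relmodel`.
#' @param path File path.
#' @export
write_model <- function(model, path) {
  hdr <- sprintf("# agmr_identical_cutoff=%.10g hgmr_unrelated_cutoff=%.10g",
                 model$agmr_identical_cutoff, model$hgmr_unrelated_cutoff)
  body <- readr::format_tsv(model$params)
  writeLines(c(hdr, sub("\n$", "", body)), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  hdr <- readLines(path, n = 1)
  vals <- sub("^[^=]*=", "", strsplit(trimws(hdr), "\\s+")[[1]][2:3])
  params <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    relationship = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  relationship_model(params,
                     agmr_identical_cutoff = as.numeric(vals[1]),
                     hgmr_unrelated_cutoff = as.numeric(vals[2]))
}
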
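#' Configuration for the synthetic fingerprint cohort generator
#'
#' The simulator draws founder genotypes under Hardy-Weinberg equilibrium in
#' a single homogeneous random-mating population, creates offspring by
#' Mendelian gene dropping (one allele transmitted per parent, independently
#' across SNPs), plants duplicate samples, and applies genotyping error,
#' random missingness and optional platform-style structural missingness.
#' All downstream modules can be validated against its known truth.
#'
#' @param S Panel size (number of SNPs), minimum 64.
#' @param freq A [freq_spec()]; per-SNP allele-1 frequencies are drawn from
#'   it once per panel (default uniform 0.1--0.9).
#' @param n_families Number of families to generate.
#' @param family_template `"nuclear"` (2 founders + 2 children),
#'   `"three_generation"` (grandparents, parent couple, 2 children),
#'   `"half_sib"` (1 shared mother, 2 fathers, 2 half siblings), or
#'   `"cousin"` (two full-sib parents married to unrelated spouses; their
#'   children are first cousins; 10 members covering PO/FS/D2/D3).
#' @param n_unrelated Additional unrelated singleton samples.
#' @param n_duplicates Planted duplicate samples: each copies the observed
#'   genotypes of a distinct existing sample and then receives fresh
#'   genotyping error, so the realized duplicate-pair mismatch rate is
#'   `error_rate`.
#' @param error_rate Per-genotype error probability; an erroneous genotype
#'   is replaced by one of the other two genotypes uniformly.
#' @param missing_rate Per-genotype missing probability (applied after
#'   error).
#' @param platform_mask Optional list of integer vectors of SNP indices;
#'   emulated dataset d lacks those SNPs entirely, and samples are assigned
#'   to datasets round-robin.
#' @param seed Random seed (deterministic output for a fixed config+seed).
#' @return A `sim_config` list.
#' @export
sim_config <- function(S = 10000, freq = freq_spec(), n_families = 0,
                       family_template = c("nuclear", "three_generation",
                                           "half_sib", "cousin"),
                       n_unrelated = 0, n_duplicates = 0, error_rate = 0,
                       missing_rate = 0, platform_mask = NULL, seed = 0) {
  family_template <- match.arg(family_template)
  stopifnot(S >= 64, error_rate >= 0, error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  structure(list(S = S, freq = freq, n_families = n_families,
                 family_template = family_template,
                 n_unrelated = n_unrelated, n_duplicates = n_duplicates,
                 error_rate = error_rate, missing_rate = missing_rate,
                 platform_mask = platform_mask, seed = seed),
            class = "sim_config")
}

#' Generate a synthetic fingerprint cohort with known truth
#'
#' @param config A [sim_config()].
#' @return A list of class `kin_sim`:
#'   * `panel`: fingerprint panel tibble (synthetic markers),
#'   * `snps`, `samples`, `genotypes`: a PLINK-style dataset (genotypes are
#'     the observed codes, SNPs x samples),
#'   * `fingerprints`: the packed `kin_fp`,
#'   * `pedigree`: a `kin_ped` (with the duplicate sample map),
#'   * `truth`: tibble of true pairwise relationships (`id_a`, `id_b`,
#'     `relationship`; pairs not listed are unrelated),
#'   * `freqs`: per-SNP allele-1 frequencies,
#'   * `config`.
#' @examples
#' sim <- simulate_cohort(sim_config(S = 256, n_families = 1,
#'                                   n_unrelated = 4, seed = 42))
#' sim$truth
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  S <- config$S
  p <- if (config$freq$kind == "explicit")
    rep_len(config$freq$freqs, S) else runif(S, config$freq$lo, config$freq$hi)

  panel <- synthetic_panel(S, p)

  # pedigree + founder/offspring genotypes
  ped_rows <- list()
  geno_cols <- list()
  founders <- function(k) matrix(rbinom(S * k, 2, 1 - p), nrow = S)
  # genotype code counts copies of allele2 (frequency 1 - p)

  drop_child <- function(gf, gm) {
    transmit <- function(g) {
      het <- g == 1L
      allele <- integer(length(g))
      allele[g == 2L] <- 1L
      allele[het] <- rbinom(sum(het), 1, 0.5)
      allele
    }
    transmit(gf) + transmit(gm)
  }

  for (f in seq_len(config$n_families)) {
    fam <- sprintf("F%03d", f)
    tpl <- family_members(config$family_template, fam)
    g <- matrix(NA_integer_, nrow = S, ncol = nrow(tpl))
    colnames(g) <- tpl$id
    is_founder <- is.na(tpl$father_id)
    g[, is_founder] <- founders(sum(is_founder))
    # children in pedigree order (parents always precede children)
    for (i in which(!is_founder))
      g[, i] <- drop_child(g[, tpl$father_id[i]], g[, tpl$mother_id[i]])
    ped_rows[[f]] <- tpl
    geno_cols[[f]] <- g
  }

  if (config$n_unrelated > 0) {
    ids <- sprintf("U%04d", seq_len(config$n_unrelated))
    tpl <- tibble::tibble(family_id = ids, id = ids,
                          father_id = NA_character_,
                          mother_id = NA_character_,
                          sex = rep(c("male", "female"),
                                    length.out = length(ids)))
    g <- founders(length(ids))
    colnames(g) <- ids
    ped_rows[[length(ped_rows) + 1]] <- tpl
    geno_cols[[length(geno_cols) + 1]] <- g
  }

  ped_tbl <- dplyr::bind_rows(ped_rows)
  geno <- do.call(cbind, geno_cols)
  true_geno <- geno

  # genotyping error on every emitted sample
  geno <- apply_error(geno, config$error_rate)

  # duplicates copy the observed genotypes, then fresh error
  sample_map <- NULL
  if (config$n_duplicates > 0) {
    stopifnot(config$n_duplicates <= ncol(geno))
    src <- seq_len(config$n_duplicates)
    dup_ids <- paste0(colnames(geno)[src], "-dup")
    gdup <- apply_error(geno[, src, drop = FALSE], config$error_rate)
    colnames(gdup) <- dup_ids
    geno <- cbind(geno, gdup)
    sample_map <- tibble::tibble(
      subject_id = c(colnames(true_geno), colnames(true_geno)[src]),
      sample_id = colnames(geno))
  }

  # random missingness, then platform-style structural missingness
  if (config$missing_rate > 0) {
    drop <- matrix(runif(length(geno)) < config$missing_rate,
                   nrow = nrow(geno))
    geno[drop] <- NA_integer_
  }
  if (!is.null(config$platform_mask)) {
    d <- length(config$platform_mask)
    assign_ds <- rep_len(seq_len(d), ncol(geno))
    for (k in seq_len(d))
      geno[config$platform_mask[[k]], assign_ds == k] <- NA_integer_
  }

  samples <- tibble::tibble(
    family_id = c(ped_tbl$family_id,
                  if (!is.null(sample_map))
                    ped_tbl$family_id[match(
                      sample_map$subject_id[-seq_len(nrow(ped_tbl))],
                      ped_tbl$id)]),
    sample_id = colnames(geno),
    father_id = NA_character_, mother_id = NA_character_,
    sex = "unknown")

  ped <- ped_graph(ped_tbl, sample_map = sample_map)
  truth <- ped_relationships(ped)

  packed <- cpp_pack(geno)
  fp <- new_kin_fp(colnames(geno), packed$hi, packed$lo,
                   packed$n_genotyped, panel)

  structure(list(panel = panel, snps = panel, samples = samples,
                 genotypes = geno, fingerprints = fp, pedigree = ped,
                 truth = truth, freqs = p, config = config),
            class = "kin_sim")
}

# replace a genotype by one of the other two codes with probability rate
apply_error <- function(geno, rate) {
  if (rate <= 0) return(geno)
  hit <- which(runif(length(geno)) < rate & !is.na(geno))
  if (!length(hit)) return(geno)
  shift <- sample(1:2, length(hit), replace = TRUE)
  geno[hit] <- (geno[hit] + shift) %% 3L
  geno
}

# synthetic well-spaced non-complementary autosomal markers, already in
# (chrom, pos) order so panel rows match genotype matrix rows
synthetic_panel <- function(S, p) {
  per <- ceiling(S / 22)
  chrom <- as.character(rep(1:22, each = per)[seq_len(S)])
  pos <- 1000000L + 60000L * (sequence(rle(chrom)$lengths) - 1L)
  pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"), nrow = 2)
  al <- pairs[, rep_len(1:4, S)]
  panel <- tibble::tibble(
    marker_id = sprintf("snp%05d", seq_len(S)),
    chrom = chrom, pos = pos, allele1 = al[1, ], allele2 = al[2, ],
    maf = pmin(p, 1 - p))
  class(panel) <- c("fp_panel", class(panel))
  panel
}

family_members <- function(template, fam) {
  nid <- function(x) paste0(fam, "_", x)
  tb <- function(id, fa, mo, sex) tibble::tibble(
    family_id = fam, id = nid(id),
    father_id = ifelse(is.na(fa), NA_character_, nid(fa)),
    mother_id = ifelse(is.na(mo), NA_character_, nid(mo)), sex = sex)
  switch(template,
    nuclear = tb(c("dad", "mom", "c1", "c2"),
                 c(NA, NA, "dad", "dad"), c(NA, NA, "mom", "mom"),
                 c("male", "female", "male", "female")),
    three_generation = tb(
      c("gf", "gm", "dad", "mom", "c1", "c2"),
      c(NA, NA, "gf", NA, "dad", "dad"),
      c(NA, NA, "gm", NA, "mom", "mom"),
      c("male", "female", "male", "female", "male", "female")),
    half_sib = tb(
      c("mom", "dad1", "dad2", "h1", "h2"),
      c(NA, NA, NA, "dad1", "dad2"),
      c(NA, NA, NA, "mom", "mom"),
      c("female", "male", "male", "male", "female")),
    cousin = tb(
      c("gf", "gm", "a", "b", "sa", "sb", "ca1", "ca2", "cb1", "cb2"),
      c(NA, NA, "gf", "gf", NA, NA, "a", "a", "sb", "sb"),
      c(NA, NA, "gm", "gm", NA, NA, "sa", "sa", "b", "b"),
      c("male", "female", "male", "female", "female", "male",
        "male", "female", "male", "female"))
  )
}

#' Score detected pairs against the simulated truth
#'
#' Compares a set of detected/classified pairs with the simulator's truth
#' table: per relationship, the number of true pairs, detected pairs,
#' correct detections, sensitivity and false discovery rate. Duplicate
#' detection is an exact set comparison on the `ID` row.
#'
#' @param truth Truth tibble (`id_a`, `id_b`, `relationship`) from
#'   [simulate_cohort()]; pairs absent from it count as unrelated.
#' @param detected Tibble with `id_a`, `id_b` and either a `relationship`
#'   column (classification) or none (duplicate scan, all `ID`).
#' @return A tibble with one row per relationship present in either set:
#'   `relationship`, `n_true`, `n_detected`, `n_correct`, `sensitivity`,
#'   `fdr`.
#' @export
plant_report <- function(truth, detected) {
  if (!"relationship" %in% names(detected))
    detected$relationship <- "ID"
  tkey <- setNames(as.character(truth$relationship),
                   pair_key(truth$id_a, truth$id_b))
  dkey <- pair_key(detected$id_a, detected$id_b)
  drel <- as.character(detected$relationship)
  rels <- union(unique(tkey), unique(drel))
  rels <- intersect(REL_LEVELS, rels)
  out <- lapply(rels, function(r) {
    true_pairs <- names(tkey)[tkey == r]
    det_pairs <- dkey[drel == r]
    n_correct <- sum(det_pairs %in% true_pairs)
    tibble::tibble(
      relationship = r, n_true = length(true_pairs),
      n_detected = length(det_pairs), n_correct = n_correct,
      sensitivity = if (length(true_pairs)) n_correct / length(true_pairs)
        else NA_real_,
      fdr = if (length(det_pairs)) 1 - n_correct / length(det_pairs)
        else NA_real_)
  })
  dplyr::bind_rows(out)
}
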
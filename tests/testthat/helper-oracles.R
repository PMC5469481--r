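# Independent scalar oracles and small fixture builders used across tests.

# Per-SNP scalar loop over genotype codes (0/1/2/NA): the reference
# implementation of the pairwise counts, independent of the bitwise kernel.
scalar_pair_counts <- function(ga, gb) {
  valid <- !is.na(ga) & !is.na(gb)
  mism <- valid & ga != gb
  bothhom <- valid & ga != 1L & gb != 1L
  do <- bothhom & ga != gb
  c(n_compared = sum(valid), n_mismatch = sum(mism),
    n_both_hom = sum(bothhom), n_DO = sum(do))
}

# Build a kin_fp directly from a genotype matrix (SNPs x samples).
fp_from_geno <- function(geno, ids = NULL, min_genotyped = 0) {
  S <- nrow(geno)
  ids <- ids %||% paste0("s", seq_len(ncol(geno)))
  colnames(geno) <- ids
  panel <- kinmatch:::synthetic_panel(S, rep(0.5, S))
  data <- list(snps = panel, samples = tibble::tibble(sample_id = ids),
               genotypes = geno)
  pack_fingerprints(data, panel, min_genotyped = min_genotyped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random genotype matrix with missingness.
random_geno <- function(S, n, miss = 0.1) {
  g <- matrix(sample(c(0:2, NA), S * n, replace = TRUE,
                     prob = c((1 - miss) / 3, (1 - miss) / 3,
                              (1 - miss) / 3, miss)),
              nrow = S)
  g
}
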
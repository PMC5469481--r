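# Fingerprint panel selection, allele harmonization, packing.

test_that("select_panel applies each fingerprinting rule", {
  cand <- tibble::tibble(
    marker_id = paste0("rs", 1:10),
    chrom = c(rep("1", 6), rep("2", 4)),
    pos = c(1e5, 1.4e5, 2e5, 3e5, 3.5e5, 5e5, 1e5, 2e5, 3e5, 4e5),
    allele1 = c("A", "A", "A", "A", "G", "A", "A", "T", "C", "A"),
    allele2 = c("G", "G", "T", "G", "C", "G", "C", "A", "G", "G"),
    maf = c(0.3, 0.3, 0.3, 0.1, 0.4, 0.3, 0.3, 0.3, 0.05, 0.2))
  suppressMessages(panel <- select_panel(cand))
  # rs2 spacing (40 kb from rs1); rs3, rs8 strand-ambiguous A/T; rs4 maf;
  # rs5 G/C ambiguous; rs9 maf and G/C
  expect_setequal(panel$marker_id, c("rs1", "rs6", "rs7", "rs10"))
  # independent per-rule oracle: re-apply each filter on its own
  expect_true(all(panel$maf > 0.17))
  expect_false(any(paste(panel$allele1, panel$allele2) %in%
                     c("A T", "T A", "G C", "C G")))
  spacing_ok <- panel |>
    dplyr::group_by(chrom) |>
    dplyr::summarise(ok = all(diff(pos) >= 50000)) |>
    dplyr::pull(ok)
  expect_true(all(spacing_ok))
})

test_that("platform-presence and greedy spacing rules work", {
  cand <- tibble::tibble(
    marker_id = c("a", "b", "c"), chrom = "1",
    pos = c(1e5, 1.4e5, 2.0e5),
    allele1 = "A", allele2 = "G", maf = 0.3)
  suppressMessages(
    panel <- select_panel(cand, platform_presence = c(a = 0.9, b = 0.5)))
  # b fails the 80% platform rule; c (unlisted -> present) is 100 kb from a
  expect_setequal(panel$marker_id, c("a", "c"))
  # two A/G SNPs 40 kb apart: greedy left-to-right keeps the first
  suppressMessages(panel2 <- select_panel(cand[1:2, ]))
  expect_equal(panel2$marker_id, "a")
})

test_that("harmonization maps every compatible orientation and no other", {
  expect_equal(harmonize_alleles("A", "G", "A", "G"), "same")
  expect_equal(harmonize_alleles("G", "A", "A", "G"), "swapped")
  expect_equal(harmonize_alleles("T", "C", "A", "G"), "flipped")
  expect_equal(harmonize_alleles("C", "T", "A", "G"), "swapped_flipped")
  expect_equal(harmonize_alleles("A", "C", "A", "G"), "incompatible")
  expect_equal(harmonize_alleles("0", "G", "A", "G"), "incompatible")
  expect_error(harmonize_alleles("A", "G", "A", "T"), "non-complementary")

  # involution: applying the reported orientation to the dataset alleles
  # recovers the panel alleles exactly
  comp <- function(x) c(A = "T", C = "G", G = "C", T = "A")[x]
  alleles <- c("A", "C", "G", "T")
  panel_pairs <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
  for (pp in panel_pairs) for (a1 in alleles) for (a2 in alleles) {
    if (a1 == a2) next
    o <- harmonize_alleles(a1, a2, pp[1], pp[2])
    back <- switch(o,
      same = c(a1, a2), swapped = c(a2, a1),
      flipped = unname(comp(c(a1, a2))),
      swapped_flipped = unname(comp(c(a2, a1))),
      incompatible = NULL)
    if (!is.null(back)) expect_equal(back, pp)
  }
})

test_that("packing encodes the documented 2-bit code table", {
  # 64 het genotypes: hi word 0, lo word all-ones
  fp <- fp_from_geno(matrix(1L, nrow = 64, ncol = 1))
  expect_equal(as.vector(fp$hi), as.raw(rep(0, 8)))
  expect_equal(as.vector(fp$lo), as.raw(rep(0xff, 8)))

  # pad bits beyond S are missing: 10 SNPs all hom-a1 -> n_genotyped 10
  fp2 <- fp_from_geno(matrix(0L, nrow = 10, ncol = 1))
  expect_equal(fp2$n_genotyped, 10L)
  expect_equal(unname(unpack_fingerprints(fp2)[, 1]), rep(0L, 10))

  # ungenotyped sample flagged
  fp3 <- fp_from_geno(matrix(NA_integer_, nrow = 70, ncol = 1),
                      min_genotyped = 1)
  expect_equal(fp3$n_genotyped, 0L)
  expect_true(fp3$flagged)
})

test_that("pack -> unpack is the identity and n_genotyped is consistent", {
  set.seed(42)
  for (S in c(64, 200, 257)) {
    g <- random_geno(S, 7, miss = 0.15)
    fp <- fp_from_geno(g)
    expect_equal(unname(unpack_fingerprints(fp)), g)
    expect_equal(fp$n_genotyped, colSums(!is.na(g)))
  }
})

test_that("pack_fingerprints harmonizes alleles and remaps swapped codes", {
  S <- 64
  panel <- kinmatch:::synthetic_panel(S, rep(0.5, S))  # A/G, A/C, T/G, T/C
  # dataset stores the same SNPs with swapped allele order -> codes flip 0<->2
  snps <- panel
  snps$allele1 <- panel$allele2
  snps$allele2 <- panel$allele1
  g <- matrix(rep_len(c(0L, 1L, 2L, NA), S), ncol = 1)
  colnames(g) <- "x"
  fp <- pack_fingerprints(list(snps = snps, genotypes = g), panel,
                          min_genotyped = 0)
  expect_equal(unname(unpack_fingerprints(fp)[, 1]),
               rep_len(c(2L, 1L, 0L, NA), S))
  # dataset on the other strand (complemented alleles) -> codes unchanged
  snps2 <- panel
  snps2$allele1 <- c(A = "T", C = "G", G = "C", T = "A")[panel$allele1]
  snps2$allele2 <- c(A = "T", C = "G", G = "C", T = "A")[panel$allele2]
  fp2 <- pack_fingerprints(list(snps = snps2, genotypes = g), panel,
                           min_genotyped = 0)
  expect_equal(unname(unpack_fingerprints(fp2)[, 1]),
               rep_len(c(0L, 1L, 2L, NA), S))
  # incompatible alleles -> encoded missing
  snps3 <- panel
  snps3$allele2 <- "0"
  fp3 <- pack_fingerprints(list(snps = snps3, genotypes = g), panel,
                           min_genotyped = 0)
  expect_equal(fp3$n_genotyped, 0L)
})

test_that("panel TSV round-trips", {
  dir <- withr::local_tempdir()
  panel <- kinmatch:::synthetic_panel(128, runif(128, 0.2, 0.8))
  path <- file.path(dir, "panel.tsv")
  write_panel(panel, path)
  back <- read_panel(path)
  expect_equal(back$marker_id, panel$marker_id)
  expect_equal(back$maf, panel$maf, tolerance = 1e-12)
})

test_that("packed fingerprints round-trip through the flat binary format", {
  dir <- withr::local_tempdir()
  set.seed(8)
  g <- random_geno(300, 5, miss = 0.1)
  fp <- fp_from_geno(g)
  path <- file.path(dir, "fp.bin")
  write_fingerprints(fp, path)
  back <- read_fingerprints(path, fp$panel, min_genotyped = 0)
  expect_equal(back$sample_id, fp$sample_id)
  expect_equal(back$n_genotyped, fp$n_genotyped)
  expect_equal(unpack_fingerprints(back), unpack_fingerprints(fp))
  expect_error(read_fingerprints(path, fp$panel[1:10, ]), "mismatch")
  # comparing across two sets built on one panel
  fp2 <- fp_from_geno(g[, c(1, 1)], ids = c("x1", "x2"))
  st <- pair_stats(fp, 1, "x2", fp_b = fp2)
  expect_equal(st$n_mismatch, 0L)
})
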
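# Pedigree graph, kinship recursion, expected relationships, QC report.

demo_ped <- function() {
  # three generations with an avuncular branch and cousins
  tibble::tibble(
    family_id = "f",
    id = c("gf", "gm", "a", "b", "sa", "sb", "ca", "cb", "h1"),
    father_id = c(NA, NA, "gf", "gf", NA, NA, "a", "sb", "gf"),
    mother_id = c(NA, NA, "gm", "gm", NA, NA, "sa", "b", NA),
    sex = c("male", "female", "male", "female", "female", "male",
            "male", "female", "male"))
}

test_that("pedigree validation catches structural errors", {
  ped <- demo_ped()
  expect_s3_class(ped_graph(ped), "kin_ped")
  bad <- ped
  bad$father_id[bad$id == "gf"] <- "ca"  # cycle: gf -> ca -> a -> gf
  expect_error(ped_graph(bad), "cycle")
  dup <- dplyr::bind_rows(ped, ped[1, ])
  expect_error(ped_graph(dup), "duplicate")
  orphanparent <- ped
  orphanparent$father_id[orphanparent$id == "ca"] <- "ghost"
  expect_error(ped_graph(orphanparent), "ghost")
})

test_that("kinship recursion reproduces textbook coefficients", {
  pg <- ped_graph(demo_ped())
  expect_equal(ped_kinship(pg, "a", "gf"), 1 / 4)     # parent-offspring
  expect_equal(ped_kinship(pg, "a", "b"), 1 / 4)      # full sibs
  expect_equal(ped_kinship(pg, "ca", "gf"), 1 / 8)    # grandparent
  expect_equal(ped_kinship(pg, "ca", "b"), 1 / 8)     # avuncular
  expect_equal(ped_kinship(pg, "a", "h1"), 1 / 8)     # half sibs (h1 no mother)
  expect_equal(ped_kinship(pg, "ca", "cb"), 1 / 16)   # first cousins
  expect_equal(ped_kinship(pg, "ca", "sb"), 0)        # married-in, unrelated
  expect_equal(ped_kinship(pg, "a", "a"), 1 / 2)      # non-inbred self
})

test_that("expected relationships cover every class and are symmetric", {
  pg <- ped_graph(demo_ped())
  cases <- list(c("a", "gf", "PO"), c("a", "b", "FS"),
                c("ca", "gf", "D2"), c("ca", "b", "D2"),
                c("a", "h1", "D2"), c("ca", "cb", "D3"),
                c("ca", "sb", "UN"), c("gf", "sb", "UN"))
  for (cs in cases) {
    expect_equal(expected_relationship(pg, cs[1], cs[2]), cs[3])
    expect_equal(expected_relationship(pg, cs[2], cs[1]), cs[3])
  }
  # great-grandparent is third degree: extend with one more generation
  ext <- dplyr::bind_rows(demo_ped(), tibble::tibble(
    family_id = "f", id = c("sca", "gca"), father_id = c(NA, "ca"),
    mother_id = c(NA, "sca"), sex = c("female", "male")))
  pg2 <- ped_graph(ext)
  expect_equal(expected_relationship(pg2, "gca", "gf"), "D3")
})

test_that("MZ twins and shared subjects map to identical", {
  ped <- demo_ped()
  pg <- ped_graph(ped, mz_twins = tibble::tibble(id_a = "ca", id_b = "cb"))
  expect_equal(expected_relationship(pg, "ca", "cb"), "ID")
  pg2 <- ped_graph(ped, sample_map = tibble::tibble(
    subject_id = c("a", "a"), sample_id = c("a_s1", "a_s2")))
  rels <- ped_relationships(pg2)
  expect_true(any(rels$id_a == "a_s1" & rels$id_b == "a_s2" &
                    rels$relationship == "ID"))
})

test_that("qc_report confirms a fully consistent simulated study", {
  sim <- simulate_cohort(sim_config(S = 10000, n_families = 6,
                                    family_template = "cousin",
                                    error_rate = 0.002, seed = 31))
  st <- pairs_stats(sim$fingerprints, sim$truth)
  st$relationship <- sim$truth$relationship
  model <- fit_model(st)
  qc <- qc_report(sim$fingerprints, sim$pedigree, model)
  expect_equal(qc$summary$category, "confirmed")
  expect_equal(sum(qc$summary$n_pairs), nrow(sim$truth))
  expect_equal(length(qc$orphans), 0)
  expect_equal(glance(qc)$confirmed, nrow(sim$truth))
})

test_that("qc_report categorises planted discrepancies", {
  # half-sib family misreported as full sibs: reattach h2 to h1's father.
  # This plants all three error categories at once:
  #   h1-h2   reported FS, genotypes D2  -> type_mismatch
  #   h2-dad1 reported PO, genotypes UN  -> reported_but_unrelated
  #   h2-dad2 unreported,  genotypes PO  -> unreported_related
  sim <- simulate_cohort(sim_config(S = 10000, n_families = 4,
                                    family_template = "half_sib",
                                    error_rate = 0.002, seed = 32))
  ped_tbl <- sim$pedigree$ped
  fam1 <- ped_tbl$family_id[1]
  id <- function(x) paste0(fam1, "_", x)
  ped_tbl$father_id[ped_tbl$id == id("h2")] <- id("dad1")
  qc <- qc_report(sim$fingerprints, ped_graph(ped_tbl), default_model())
  rec <- qc$discrepancies
  by_cat <- split(rec, rec$category)
  expect_equal(nrow(by_cat$type_mismatch), 1)
  expect_equal(by_cat$type_mismatch$reported, "FS")
  expect_equal(by_cat$type_mismatch$predicted, "D2")
  expect_equal(sort(c(by_cat$reported_but_unrelated$id_a,
                      by_cat$reported_but_unrelated$id_b)),
               sort(c(id("h2"), id("dad1"))))
  expect_equal(sort(c(by_cat$unreported_related$id_a,
                      by_cat$unreported_related$id_b)),
               sort(c(id("h2"), id("dad2"))))
  # two truth pairs turned discrepant; all other truth pairs stay confirmed
  expect_equal(nrow(by_cat$confirmed), nrow(sim$truth) - 2)

  # an unreported planted duplicate is flagged duplicate_unreported
  sim2 <- simulate_cohort(sim_config(S = 10000, n_unrelated = 8,
                                     n_duplicates = 1, error_rate = 0.002,
                                     seed = 33))
  ped_no_map <- ped_graph(sim2$pedigree$ped)  # drop the sample map
  qc2 <- qc_report(sim2$fingerprints, ped_no_map, default_model())
  expect_equal(qc2$summary$n_pairs[qc2$summary$category ==
                                     "duplicate_unreported"], 1L)
})

test_that("reported-identical pairs with sibling-like AGMR are flagged DZ", {
  sim <- simulate_cohort(sim_config(S = 10000, n_families = 2,
                                    family_template = "nuclear",
                                    error_rate = 0.002, seed = 34))
  # report the two full sibs of family 1 as MZ twins
  sibs <- sim$truth[sim$truth$relationship == "FS", ][1, ]
  pg <- ped_graph(sim$pedigree$ped,
                  mz_twins = tibble::tibble(id_a = sibs$id_a,
                                            id_b = sibs$id_b))
  qc <- qc_report(sim$fingerprints, pg, default_model())
  expect_gte(nrow(qc$flags), 1)
  expect_match(qc$flags$note[1], "DZ")
})
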
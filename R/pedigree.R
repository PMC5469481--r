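#' Build a pedigree graph
#'
#' Validates a PED-style table (family, individual, father, mother, sex)
#' into a pedigree object used to derive expected pairwise relationships.
#' Monozygotic twins cannot be expressed in PED columns and must be
#' annotated explicitly; a subject-to-sample mapping allows several genotyped
#' samples per subject (such samples are expected to be identical).
#'
#' @param ped Tibble with columns `family_id`, `id`, `father_id`,
#'   `mother_id`, `sex` (missing parents as `NA` or `"0"`).
#' @param mz_twins Optional tibble with columns `id_a`, `id_b` of
#'   monozygotic twin pairs.
#' @param sample_map Optional tibble with columns `subject_id`, `sample_id`
#'   mapping genotyped samples to pedigree subjects; defaults to identity.
#' @return An object of class `kin_ped`.
#' @examples
#' ped <- tibble::tibble(
#'   family_id = "f1", id = c("dad", "mom", "kid1", "kid2"),
#'   father_id = c(NA, NA, "dad", "dad"), mother_id = c(NA, NA, "mom", "mom"),
#'   sex = c("male", "female", "male", "female"))
#' expected_relationship(ped_graph(ped), "kid1", "kid2")  # FS
#' @export
ped_graph <- function(ped, mz_twins = NULL, sample_map = NULL) {
  ped <- tibble::as_tibble(ped)
  stopifnot(all(c("family_id", "id", "father_id", "mother_id") %in%
                  names(ped)))
  if (!"sex" %in% names(ped)) ped$sex <- "unknown"
  ped$father_id[ped$father_id %in% "0"] <- NA_character_
  ped$mother_id[ped$mother_id %in% "0"] <- NA_character_
  if (anyDuplicated(ped$id))
    stop("duplicate individual IDs in pedigree")
  missing_parents <- setdiff(
    stats::na.omit(c(ped$father_id, ped$mother_id)), ped$id)
  if (length(missing_parents))
    stop("parents not present as individuals: ",
         paste(missing_parents, collapse = ", "))
  check_acyclic(ped)
  if (!is.null(mz_twins))
    stopifnot(all(c("id_a", "id_b") %in% names(mz_twins)),
              all(c(mz_twins$id_a, mz_twins$id_b) %in% ped$id))
  if (!is.null(sample_map))
    stopifnot(all(c("subject_id", "sample_id") %in% names(sample_map)))
  structure(list(ped = ped, mz_twins = mz_twins, sample_map = sample_map),
            class = "kin_ped")
}

# Depth-first cycle check: no individual may be its own ancestor.
check_acyclic <- function(ped) {
  idx <- setNames(seq_len(nrow(ped)), ped$id)
  state <- integer(nrow(ped))  # 0 unseen, 1 in progress, 2 done
  visit <- function(i) {
    if (state[i] == 1L) stop("pedigree cycle detected at individual ",
                             ped$id[i])
    if (state[i] == 2L) return(invisible())
    state[i] <<- 1L
    for (p in c(ped$father_id[i], ped$mother_id[i])) {
      if (!is.na(p)) visit(idx[[p]])
    }
    state[i] <<- 2L
    invisible()
  }
  for (i in seq_len(nrow(ped))) visit(i)
  invisible(TRUE)
}

#' @export
print.kin_ped <- function(x, ...) {
  cat("<kin_ped> ", nrow(x$ped), " individuals, ",
      length(unique(x$ped$family_id)), " families",
      if (!is.null(x$mz_twins)) paste0(", ", nrow(x$mz_twins),
                                       " MZ twin pair(s)"), "\n", sep = "")
  invisible(x)
}

#' Pedigree kinship coefficients
#'
#' Computes kinship coefficients by the standard recursion: founders are
#' unrelated and non-inbred, `phi(a, a) = (1 + phi(father, mother)) / 2`,
#' and for distinct individuals `phi(a, b)` averages the kinship of `b` with
#' `a`'s parents, recursing on the individual that is not an ancestor of the
#' other.
#'
#' @param ped A `kin_ped` object (or PED-style tibble).
#' @param a,b Individual IDs.
#' @return Kinship coefficient `phi(a, b)`.
#' @export
ped_kinship <- function(ped, a, b) {
  if (!inherits(ped, "kin_ped")) ped <- ped_graph(ped)
  tbl <- ped$ped
  idx <- setNames(seq_len(nrow(tbl)), tbl$id)
  depth <- ped_depths(tbl, idx)
  fa <- match(tbl$father_id, tbl$id)
  mo <- match(tbl$mother_id, tbl$id)
  cache <- new.env(parent = emptyenv())
  phi <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    if (i > j) { t <- i; i <- j; j <- t }
    key <- paste0(i, ".", j)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (i == j) {
      (1 + phi(fa[i], mo[i])) / 2
    } else {
      # recurse on the individual deeper in the pedigree; it cannot be an
      # ancestor of the shallower one
      if (depth[i] >= depth[j]) (phi(fa[i], j) + phi(mo[i], j)) / 2
      else (phi(fa[j], i) + phi(mo[j], i)) / 2
    }
    cache[[key]] <- val
    val
  }
  ai <- idx[[a]]; bi <- idx[[b]]
  if (is.null(ai) || is.null(bi)) stop("individual not in pedigree")
  phi(ai, bi)
}

# generation depth: founders 0, child = 1 + max(parent depths)
ped_depths <- function(tbl, idx) {
  depth <- rep(NA_integer_, nrow(tbl))
  get <- function(i) {
    if (!is.na(depth[i])) return(depth[i])
    f <- tbl$father_id[i]; m <- tbl$mother_id[i]
    d <- 0L
    if (!is.na(f)) d <- max(d, get(idx[[f]]) + 1L)
    if (!is.na(m)) d <- max(d, get(idx[[m]]) + 1L)
    depth[i] <<- d
    d
  }
  for (i in seq_len(nrow(tbl))) get(i)
  depth
}

#' Expected relationship of two pedigree members
#'
#' Maps pedigree structure to the relationship classes used by the
#' classifier: `ID` for the same subject (via the sample map) or annotated
#' MZ twins; `PO` for a parent edge; `FS` when both parents are shared (and
#' the pair is not MZ); otherwise by kinship coefficient, `phi = 1/8` giving
#' `D2` (grandparent-grandchild, avuncular, half sibling), `phi = 1/16`
#' giving `D3` (first cousin, half-avuncular, great-grandparent), and
#' anything more distant `UN`. Compound relationships are classified by
#' their total kinship. Assumes no inbreeding among founders.
#'
#' @param ped A `kin_ped`.
#' @param a,b Subject IDs (symmetric).
#' @return One of `"ID"`, `"PO"`, `"FS"`, `"D2"`, `"D3"`, `"UN"`.
#' @export
expected_relationship <- function(ped, a, b) {
  stopifnot(inherits(ped, "kin_ped"))
  if (a == b) return("ID")
  if (!is.null(ped$mz_twins)) {
    tw <- ped$mz_twins
    if (any((tw$id_a == a & tw$id_b == b) | (tw$id_a == b & tw$id_b == a)))
      return("ID")
  }
  tbl <- ped$ped
  ra <- tbl[tbl$id == a, ]; rb <- tbl[tbl$id == b, ]
  if (nrow(ra) != 1 || nrow(rb) != 1) stop("individual not in pedigree")
  if (a %in% c(rb$father_id, rb$mother_id) ||
      b %in% c(ra$father_id, ra$mother_id)) return("PO")
  shared_both <- !is.na(ra$father_id) && !is.na(ra$mother_id) &&
    identical(ra$father_id, rb$father_id) &&
    identical(ra$mother_id, rb$mother_id)
  if (shared_both) return("FS")
  k <- ped_kinship(ped, a, b)
  if (k >= 1 / 4) "FS"          # compound relationship totalling first degree
  else if (k >= 1 / 8) "D2"
  else if (k >= 1 / 16) "D3"
  else "UN"
}

#' All expected relationships within a pedigree
#'
#' Tabulates [expected_relationship()] for every pair of pedigree subjects,
#' plus `ID` rows for multiple samples of one subject and MZ twins.
#' Families are unrelated to one another, so only within-family pairs (plus
#' mapped duplicates) can be non-`UN`; pairs not listed are `UN`.
#'
#' @param ped A `kin_ped`.
#' @param include_un Keep `UN` pairs in the output (default `FALSE`).
#' @return Tibble with `id_a`, `id_b`, `relationship`.
#' @export
ped_relationships <- function(ped, include_un = FALSE) {
  stopifnot(inherits(ped, "kin_ped"))
  tbl <- ped$ped
  fams <- split(tbl$id, tbl$family_id)
  rows <- list()
  for (ids in fams) {
    if (length(ids) < 2) next
    cmb <- utils::combn(ids, 2)
    rel <- vapply(seq_len(ncol(cmb)), function(k)
      expected_relationship(ped, cmb[1, k], cmb[2, k]), character(1))
    rows[[length(rows) + 1]] <-
      tibble::tibble(id_a = cmb[1, ], id_b = cmb[2, ], relationship = rel)
  }
  out <- dplyr::bind_rows(
    tibble::tibble(id_a = character(), id_b = character(),
                   relationship = character()), rows)
  if (!include_un) out <- out[out$relationship != "UN", ]
  # samples of the same subject are identical pairs
  if (!is.null(ped$sample_map)) {
    sm <- ped$sample_map
    dup <- split(sm$sample_id, sm$subject_id)
    dup <- dup[lengths(dup) > 1]
    for (ids in dup) {
      cmb <- utils::combn(sort(ids), 2)
      out <- dplyr::bind_rows(out, tibble::tibble(
        id_a = cmb[1, ], id_b = cmb[2, ], relationship = "ID"))
    }
  }
  out
}

#' Compare genotype-predicted and pedigree-reported relationships
#'
#' Classifies every sample pair from its genotypes, derives the reported
#' relationship of the corresponding subjects from the pedigree, and
#' reconciles the two. Every pair that is reported related or predicted
#' related appears exactly once, in one category:
#' * `confirmed`: reported and predicted agree,
#' * `type_mismatch`: both related, different type,
#' * `unreported_related`: predicted PO/FS/D2/D3, nothing reported,
#' * `duplicate_unreported`: predicted ID, nothing reported,
#' * `reported_but_unrelated`: reported related, predicted UN.
#'
#' The summary additionally flags reported-identical (MZ) pairs whose AGMR
#' sits near the full-sibling expectation (probably DZ twins), and
#' reported-identical pairs with AGMR near the unrelated expectation
#' (probable sample mix-ups).
#'
#' @param fp A `kin_fp` fingerprint set.
#' @param ped A `kin_ped` pedigree (with optional sample map / MZ twins).
#' @param model A `kin_relmodel` (default [default_model()]).
#' @param min_compared Minimum jointly genotyped SNPs per pair.
#' @return A list of class `kin_qc`: `discrepancies` (tibble with
#'   `id_a`, `id_b`, `reported`, `predicted`, `category` and the pair
#'   statistics), `summary` (counts per category), `flags` (suspicious
#'   reported-identical pairs) and `orphans` (sample IDs not mappable to the
#'   pedigree).
#' @export
qc_report <- function(fp, ped, model = default_model(), min_compared = 64) {
  stopifnot(inherits(fp, "kin_fp"), inherits(ped, "kin_ped"))
  sample_to_subject <- setNames(fp$sample_id, fp$sample_id)
  if (!is.null(ped$sample_map))
    sample_to_subject[ped$sample_map$sample_id] <- ped$sample_map$subject_id
  subj <- sample_to_subject[fp$sample_id]
  orphans <- fp$sample_id[!(subj %in% ped$ped$id)]

  pred <- classify_pairs(all_pairs_stats(fp, min_compared), model)
  reported <- ped_relationships(ped)
  rep_key <- setNames(reported$relationship,
                      pair_key(reported$id_a, reported$id_b))

  sa <- unname(subj[pred$id_a])
  sb <- unname(subj[pred$id_b])
  # reported relationship at subject level; same subject = reported ID
  rep_rel <- rep_key[pair_key(sa, sb)]
  rep_rel[is.na(rep_rel) & !is.na(sa) & !is.na(sb) & sa == sb] <- "ID"
  pred$reported <- unname(rep_rel)
  pred$predicted <- as.character(pred$relationship)

  keep <- (!is.na(pred$reported)) | pred$predicted != "UN"
  rec <- pred[keep & pred$comparable, ]
  rec$category <- dplyr::case_when(
    !is.na(rec$reported) & rec$reported == rec$predicted ~ "confirmed",
    is.na(rec$reported) & rec$predicted == "ID" ~ "duplicate_unreported",
    is.na(rec$reported) ~ "unreported_related",
    rec$predicted == "UN" ~ "reported_but_unrelated",
    TRUE ~ "type_mismatch"
  )

  fs_agmr <- expected_agmr("FS")
  un_agmr <- expected_agmr("UN")
  rep_id <- rec[!is.na(rec$reported) & rec$reported == "ID", ]
  flags <- tibble::tibble(
    id_a = character(), id_b = character(), agmr = numeric(),
    note = character())
  if (nrow(rep_id)) {
    dz <- abs(rep_id$agmr - fs_agmr) < 0.06
    mix <- abs(rep_id$agmr - un_agmr) < 0.06
    flags <- dplyr::bind_rows(
      tibble::tibble(id_a = rep_id$id_a[dz], id_b = rep_id$id_b[dz],
                     agmr = rep_id$agmr[dz],
                     note = "reported identical, AGMR near full-sibling expectation (probably DZ twins)"),
      tibble::tibble(id_a = rep_id$id_a[mix], id_b = rep_id$id_b[mix],
                     agmr = rep_id$agmr[mix],
                     note = "reported identical, AGMR near unrelated expectation (probable mix-up)"))
  }

  summary <- rec |>
    dplyr::count(.data$category, name = "n_pairs") |>
    dplyr::arrange(.data$category)
  drop <- c("relationship", paste0("post_", c("PO", "FS", "D2", "D3")))
  rec <- rec[, setdiff(names(rec), drop)]
  structure(list(discrepancies = rec, summary = summary, flags = flags,
                 orphans = orphans),
            class = "kin_qc")
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' @export
print.kin_qc <- function(x, ...) {
  cat("<kin_qc> pairwise pedigree concordance\n")
  print(x$summary)
  if (nrow(x$flags)) {
    cat("flagged reported-identical pairs:\n")
    print(x$flags)
  }
  if (length(x$orphans))
    cat(length(x$orphans), "sample(s) not mappable to the pedigree\n")
  invisible(x)
}

#' @export
tidy.kin_qc <- function(x, ...) x$discrepancies

#' @export
glance.kin_qc <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "category",
                     values_from = "n_pairs")
}
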
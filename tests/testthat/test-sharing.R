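make_paired_cells <- function(tumour_keys, blood_keys,
                              patient_id = "P1") {
  rbind(
    toy_cells(tumour_keys, sample_id = paste0(patient_id, "_T"),
              patient_id = patient_id, compartment = "tumour"),
    toy_cells(blood_keys, sample_id = paste0(patient_id, "_B"),
              patient_id = patient_id, compartment = "pbmc",
              timepoint = "W0")
  )
}

test_that("baseline sharing handles disjoint and identical repertoires", {
  dis <- make_paired_cells(c("a", "b"), c("c", "d"))
  r <- baselineSharing(dis)
  expect_equal(r$summary$n_shared, 0)
  expect_equal(r$summary$prop_shared_tcrs_tumour, 0)
  expect_equal(r$summary$prop_shared_cells_blood, 0)

  same <- make_paired_cells(c("a", "b", "b"), c("a", "b"))
  r <- baselineSharing(same)
  expect_equal(r$summary$prop_shared_tcrs_tumour, 1)
  expect_equal(r$summary$prop_shared_tcrs_blood, 1)
  expect_equal(r$summary$prop_shared_cells_blood, 1)
})

test_that("the shared set is symmetric; only denominators differ", {
  cells <- make_paired_cells(c("a", "a", "b", "c"), c("b", "c", "d"))
  r <- baselineSharing(cells)
  expect_setequal(r$shared_keys$P1, c("b", "c"))
  expect_equal(r$summary$prop_shared_tcrs_tumour, 2 / 3)
  expect_equal(r$summary$prop_shared_tcrs_blood, 2 / 3)
  expect_equal(r$summary$prop_shared_cells_tumour, 2 / 4)
})

test_that("patients without both compartments are omitted with a note", {
  cells <- rbind(make_paired_cells(c("a"), c("a")),
                 toy_cells("z", patient_id = "P2",
                           compartment = "tumour"))
  expect_message(r <- baselineSharing(cells), "P2")
  expect_equal(r$summary$patient_id, "P1")
})

test_that("duplicate samples require an explicit merge policy", {
  cells <- rbind(
    toy_cells(c("a", "b"), sample_id = "T1", compartment = "tumour"),
    toy_cells(c("b", "c"), sample_id = "T2", compartment = "tumour"),
    toy_cells(c("a"), sample_id = "B1", compartment = "pbmc",
              timepoint = "W0"))
  expect_error(baselineSharing(cells, merge_duplicates = FALSE),
               "merge")
  r <- baselineSharing(cells)      # default merges the two biopsies
  expect_equal(r$summary$n_tcrs_tumour, 3)
})

test_that("sharing on a synthetic cohort recovers planted truth exactly", {
  coh <- generateCohort(small_cohort_config(seed = 5))
  cells <- cohortCells(coh)
  r <- baselineSharing(cells)
  tr <- cohortTruth(coh)
  for (p in r$summary$patient_id) {
    expect_setequal(r$shared_keys[[p]], tr$patients[[p]]$shared_keys)
    expect_equal(r$summary$prop_shared_tcrs_tumour[
      r$summary$patient_id == p],
      tr$patients[[p]]$realized_sharing)
  }
})

test_that("per-phenotype shared fractions match a counting oracle", {
  cells <- toy_cells(paste0("k", 1:50),
                     phenotype = sample(c("CD8 TEM", "CD8 TEMRA",
                                          "CD8 TEX"), 50, replace = TRUE))
  expect_equal(unname(phenotypeSharedFraction(cells, character(0))),
               rep(0, length(unique(cells$phenotype))))
  expect_equal(unname(phenotypeSharedFraction(cells, paste0("k", 1:50))),
               rep(1, length(unique(cells$phenotype))))

  shared <- paste0("k", sample(1:50, 20))
  got <- phenotypeSharedFraction(cells, shared)
  for (ph in names(got)) {
    sub <- cells[cells$phenotype == ph, ]
    expect_equal(got[[ph]], sum(sub$clonotype_key %in% shared) / nrow(sub))
  }
  # cell-count weighted fractions add up to the total shared-cell count
  n_by_ph <- table(cells$phenotype)
  expect_equal(sum(got[names(n_by_ph)] * n_by_ph),
               sum(cells$clonotype_key %in% shared))
})

test_that("clonotype tracking counts matches per timepoint", {
  tum <- toy_cells(c("a", "a", "b"), compartment = "tumour",
                   phenotype = "CD8 TEMRA")
  blood <- rbind(
    toy_cells(c("a", "c", "c"), sample_id = "B0", compartment = "pbmc",
              timepoint = "W0", phenotype = "CD8 TEMRA"),
    toy_cells(c("c", "d"), sample_id = "B3", compartment = "pbmc",
              timepoint = "W3", phenotype = "CD8 TEM"))
  tr <- trackClonotypes(tum, blood, "CD8 TEMRA")
  expect_equal(tr$timepoint, c("W0", "W3"))
  expect_equal(tr$fraction, c(1 / 3, 0))
  expect_setequal(attr(tr, "source_keys"), c("a", "b"))

  # source clonotypes absent from all blood
  none <- trackClonotypes(toy_cells("z", phenotype = "CD8 TEX"),
                          blood, "CD8 TEX")
  expect_equal(none$fraction, c(0, 0))

  expect_error(trackClonotypes(tum, blood, "CD4 TREG"), "valid labels")
  expect_error(trackClonotypes(tum, blood, "CD8 TEMRA",
                               denominator_phenotypes = "bogus"),
               "valid labels")
})

test_that("tracking on a persistent cohort keeps planted keys visible", {
  cfg <- small_cohort_config(seed = 9, persistence = 1,
                             sharing_rate_resp = 0.2,
                             sharing_rate_nonresp = 0.2)
  coh <- generateCohort(cfg)
  cells <- cohortCells(coh)
  tr <- cohortTruth(coh)
  for (p in names(tr$patients)[1:3]) {
    planted <- tr$patients[[p]]$shared_keys
    if (!length(planted)) next
    blood <- cells[cells$patient_id == p & cells$compartment == "pbmc", ]
    for (tp in c("W0", "W3", "W6"))
      expect_true(all(planted %in%
                        blood$clonotype_key[blood$timepoint == tp]))
    # fractions recomputed from raw cells equal the module's answer
    tum <- cells[cells$patient_id == p & cells$compartment == "tumour", ]
    got <- trackClonotypes(tum, blood, "CD8 TEMRA")
    keys <- unique(tum$clonotype_key[tum$phenotype == "CD8 TEMRA"])
    for (i in seq_len(nrow(got))) {
      d <- blood[blood$timepoint == got$timepoint[i] &
                   grepl("^CD8", blood$phenotype), ]
      expect_equal(got$fraction[i], mean(d$clonotype_key %in% keys))
    }
  }
})

test_that("shared-TCR weight is the asymmetric upstream overlap", {
  a <- ClonotypeTable(setNames(rep(1, 4), c("x", "y", "z", "w")))
  b <- ClonotypeTable(setNames(rep(1, 3), c("y", "w", "q")))
  expect_equal(sharedTcrWeight(a, b), 0.5)
  expect_equal(sharedTcrWeight(a, a), 1)
  expect_equal(sharedTcrWeight(
    a, ClonotypeTable(setNames(1, "none"))), 0)
  expect_error(sharedTcrWeight(ClonotypeTable(numeric(0)), a),
               "no clonotypes")
  # asymmetry: same intersection, different denominator
  expect_equal(sharedTcrWeight(b, a), 2 / 3)
})
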
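# Input/output difference indicators.

test_that("dedis is the Euclidean distance to the all-ones vector", {
  expect_equal(dedis(c(1, 1, 10)), 9)
  expect_equal(dedis(c(1, 1, 10), c(1, 1, 10)), 0)
  expect_equal(dedis(c(4, 1), c(1, 1)), 3)
  x <- dosage_vector(c("a", "b", "c"), c(1, 1, 10), standardize = FALSE)
  expect_equal(dedis(x), 9)
  expect_error(dedis(c(1, 2), c(1, 2, 3)), class = "dosenet_validation_error")
  y <- dosage_vector(c("a", "c", "b"), c(1, 1, 1), standardize = FALSE)
  expect_error(dedis(x, y), class = "dosenet_validation_error")
})

test_that("desd is the sample standard deviation (n - 1 denominator)", {
  expect_equal(desd(c(1, 1, 1)), 0)
  expect_equal(desd(c(1, 1, 10)), sqrt(27))
  expect_equal(desd(c(1, 3)), sqrt(2))
  expect_equal(desd(ones_vector(5)), 0)
  expect_error(desd(1), class = "dosenet_validation_error")
})

test_that("set_difference is 1 - Jaccard with the empty pair defined as 0", {
  expect_equal(set_difference(c("A", "B"), c("A", "B")), 0)
  expect_equal(set_difference(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  expect_equal(set_difference("A", "B"), 1)
  expect_equal(set_difference(character(), character()), 0)
  expect_equal(set_difference(character(), "A"), 1)
})

test_that("set_difference matches brute force over a 5-element universe", {
  universe <- letters[1:5]
  subsets <- lapply(0:31, function(mask) universe[bitwAnd(mask, 2^(0:4)) > 0])
  for (s1 in subsets) {
    for (s2 in subsets) {
      # oracle by elementwise membership counting, independent of set ops
      in1 <- universe %in% s1
      in2 <- universe %in% s2
      n_union <- sum(in1 | in2)
      expected <- if (n_union == 0) 0 else 1 - sum(in1 & in2) / n_union
      expect_identical(set_difference(s1, s2), expected)
      expect_identical(set_difference(s2, s1), expected) # symmetry
      expect_true(expected >= 0 && expected <= 1)
    }
  }
})

test_that("metabolite-level vectors sum parent dosages, sorted by id", {
  maps <- component_map(
    tibble::tibble(
      drug_id = c("d1", "d1", "d2"),
      metabolite_id = c("m1", "m2", "m3")
    ),
    tibble::tibble(
      metabolite_id = c("m1", "m2", "m3"), gene_symbol = "T1"
    )
  )
  dv <- dosage_vector(c("d1", "d2"), c(1, 10), standardize = FALSE)
  mv <- metabolite_dosage_vector(dv, maps)
  expect_identical(mv$metabolite_id, c("m1", "m2", "m3"))
  expect_identical(mv$value, c(1, 1, 10))

  ones <- ones_vector(drug_ids = c("d1", "d2"))
  expect_identical(metabolite_dosage_vector(ones, maps)$value, c(1, 1, 1))

  shared <- metabolite_dosage_vector(
    dosage_vector(c("d1", "d2"), c(1, 10), standardize = FALSE),
    shared_metabolite_map()
  )
  expect_identical(shared$value[shared$metabolite_id == "m1"], 11)

  expect_error(
    metabolite_dosage_vector(
      dosage_vector("ghost", 1, standardize = FALSE), maps
    ),
    class = "dosenet_validation_error"
  )
})

test_that("equal-dosage prescriptions give an all-zero indicator panel", {
  b <- small_ensemble(seed = 21, n = 1, null_fraction = 1)[[1]]
  cmp <- compare_prescription(
    b$records, b$maps, b$disease_targets, b$gene_sets,
    min_genes = 3
  )
  expect_identical(unname(unlist(cmp$panel)), rep(0, 6))
  expect_identical(
    cmp$predictions$nondosage$drug_targets,
    cmp$predictions$weighted$drug_targets
  )
})

test_that("the worked-example fixture reproduces its hand-derived panel", {
  fx <- chong_he_fixture()
  cmp <- compare_prescription(
    fx$records, fx$maps, fx$disease_targets, fx$gene_sets,
    min_genes = 2
  )
  expect_equal(cmp$panel$dedis, 9)
  expect_equal(cmp$panel$desd, sqrt(27))
  # four unshared metabolites weighted [1, 1, 10, 10]
  expect_equal(cmp$panel$compound_dedis, sqrt(2 * 81))
  expect_equal(cmp$panel$compound_desd, sd(c(1, 1, 10, 10)))
  expect_equal(cmp$panel$dedt, 0.5)
  expect_equal(cmp$panel$depy, 0.5)
  # the weighted prediction strictly extends the non-dosage one, and the
  # gained targets belong to the ten-fold-dosed drug
  s1 <- cmp$predictions$nondosage$drug_targets
  s2 <- cmp$predictions$weighted$drug_targets
  expect_true(all(s1 %in% s2) && length(s2) > length(s1))
  expect_identical(setdiff(s2, s1), c("G03", "G04"))
})

test_that("pathway stage degrades gracefully without gene sets", {
  fx <- chong_he_fixture()
  cmp <- compare_prescription(fx$records, fx$maps, fx$disease_targets)
  expect_true(is.na(cmp$panel$depy))
  expect_equal(cmp$panel$dedt, 0.5) # target indicators still computed
  expect_null(cmp$enrichment$nondosage)
})

test_that("zero input distance forces zero output change, not conversely", {
  # necessity direction over random equal-dosage bundles
  for (b in small_ensemble(seed = 31, n = 6, null_fraction = 1)) {
    cmp <- compare_prescription(
      b$records, b$maps, b$disease_targets, b$gene_sets,
      min_genes = 3
    )
    expect_identical(cmp$panel$dedis, 0)
    expect_identical(cmp$panel$dedt, 0)
    expect_identical(cmp$panel$depy, 0)
  }
  # converse is false: a small dosage change leaves predictions intact
  fx <- chong_he_fixture()
  rec <- dplyr::mutate(fx$records, quantity = c(1, 1, 1.1), unit = "gram")
  cmp <- compare_prescription(
    rec, fx$maps, fx$disease_targets, fx$gene_sets,
    min_genes = 2
  )
  expect_gt(cmp$panel$dedis, 0)
  expect_identical(cmp$panel$dedt, 0)
  expect_identical(cmp$panel$depy, 0)
})

test_that("dedis and desd are positively correlated over ensembles", {
  panels <- batch_indicators(small_ensemble(seed = 41, n = 20),
    use_gene_sets = FALSE
  )
  res <- pearson_cor_test(panels$dedis, panels$desd)
  expect_gt(res$estimate, 0)
})

test_that("tidy and glance summarize a comparison", {
  fx <- chong_he_fixture()
  cmp <- compare_prescription(
    fx$records, fx$maps, fx$disease_targets, fx$gene_sets,
    min_genes = 2
  )
  long <- tidy(cmp)
  expect_identical(nrow(long), 6L)
  expect_identical(
    long$indicator,
    c("dedis", "desd", "compound_dedis", "compound_desd", "dedt", "depy")
  )
  g <- glance(cmp)
  expect_identical(g$n_drugs, 3L)
  expect_identical(g$n_drug_targets_nondosage, 2L)
  expect_identical(g$n_drug_targets_weighted, 4L)
  expect_equal(g$dedis, 9)
})
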
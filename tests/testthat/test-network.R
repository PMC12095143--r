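# Layered network construction, weighted degree, key-target selection.

test_that("all-ones dosage with unshared metabolites gives unit weights", {
  fx <- chong_he_fixture()
  net <- build_network(
    ones_vector(drug_ids = fx$records$drug_id), fx$maps, fx$disease_targets
  )
  expect_true(all(net$edges$weight == 1))
})

test_that("dosage propagates along drug edges and sums over shared parents", {
  # single path: drug weight 10 reaches its target edge
  single <- component_map(
    tibble::tibble(drug_id = "d1", metabolite_id = "m1"),
    tibble::tibble(metabolite_id = "m1", gene_symbol = "T1")
  )
  net <- build_network(
    dosage_vector("d1", 10, standardize = FALSE), single, character()
  )
  mt <- net$edges[net$edges$layer_pair == "metabolite-target", ]
  expect_equal(mt$weight, 10)

  # shared metabolite: parents weighted 1 and 10 -> target edge 11
  dv <- dosage_vector(c("d1", "d2"), c(1, 10), standardize = FALSE)
  net2 <- build_network(dv, shared_metabolite_map(), character())
  e <- net2$edges
  expect_equal(
    e$weight[e$from == "m1" & e$to == "T1"], 11
  )
  net2max <- build_network(dv, shared_metabolite_map(), character(),
    propagate = "max"
  )
  e <- net2max$edges
  expect_equal(e$weight[e$from == "m1" & e$to == "T1"], 10)
})

test_that("duplicate input edges are collapsed before weighting", {
  dup <- component_map(
    tibble::tibble(
      drug_id = c("d1", "d1", "d1"),
      metabolite_id = c("m1", "m1", "m1")
    ),
    tibble::tibble(
      metabolite_id = c("m1", "m1"), gene_symbol = c("T1", "T1")
    )
  )
  net <- build_network(
    dosage_vector("d1", 3, standardize = FALSE), dup, character()
  )
  expect_equal(nrow(net$edges), 2)
  expect_equal(sum(net$edges$layer_pair == "metabolite-target"), 1)
})

test_that("unmapped drugs abort network construction", {
  expect_error(
    build_network(ones_vector(drug_ids = c("d1", "ghost")),
      shared_metabolite_map(), character()
    ),
    "ghost",
    class = "dosenet_validation_error"
  )
})

test_that("weighted degree sums incident edge weights", {
  # star: center with 4 unit leaves
  star <- prescription_network(
    tibble::tibble(
      node = c("m", "t1", "t2", "t3", "t4"),
      layer = c("metabolite", rep("target", 4))
    ),
    tibble::tibble(
      from = "m", to = paste0("t", 1:4),
      layer_pair = "metabolite-target", weight = 1
    )
  )
  expect_equal(weighted_degree(star, "m")$degree, 4)
  expect_equal(weighted_degree(star, "t1")$degree, 1)

  # two metabolites of weight 1 and 10 on one target
  two <- prescription_network(
    tibble::tibble(
      node = c("m1", "m2", "t", "iso"),
      layer = c("metabolite", "metabolite", "target", "target")
    ),
    tibble::tibble(
      from = c("m1", "m2"), to = "t",
      layer_pair = "metabolite-target", weight = c(1, 10)
    )
  )
  expect_equal(weighted_degree(two, "t")$degree, 11)
  expect_equal(weighted_degree(two, "iso")$degree, 0) # isolated node
  expect_error(weighted_degree(two, "nope"),
    class = "dosenet_validation_error"
  )
})

test_that("weighted degree matches adjacency-matrix row sums", {
  for (b in small_ensemble(seed = 3, n = 4)) {
    dv <- standardize_dosage(b$records)
    net <- build_network(dv, b$maps, b$disease_targets)
    deg <- weighted_degree(net)
    oracle <- adjacency_degrees(net)
    expect_equal(
      stats::setNames(deg$degree, deg$node), oracle[deg$node]
    )
  }
})

test_that("unit-weight degree equals the graph-theoretic degree", {
  # metabolites unshared between drugs, so the all-ones network really
  # has unit weights everywhere
  fx <- chong_he_fixture()
  net <- build_network(
    ones_vector(drug_ids = fx$records$drug_id), fx$maps, fx$disease_targets
  )
  expect_true(all(net$edges$weight == 1))
  deg <- weighted_degree(net)
  edge_count <- table(c(net$edges$from, net$edges$to))
  expect_equal(deg$degree, as.numeric(edge_count[deg$node]))
})

test_that("key targets strictly exceed the target-layer mean degree", {
  # degrees [3,1,1,1]: mean 1.5 -> only T1 is key
  maps <- component_map(
    tibble::tibble(drug_id = "d1", metabolite_id = c("m1", "m2", "m3")),
    tibble::tibble(
      metabolite_id = c("m1", "m1", "m2", "m2", "m3", "m3"),
      gene_symbol = c("T1", "T2", "T1", "T3", "T1", "T4")
    )
  )
  net <- build_network(ones_vector(drug_ids = "d1"), maps, character())
  pred <- select_key_targets(net)
  expect_equal(
    stats::setNames(pred$degree_table$degree, pred$degree_table$node),
    c(T1 = 3, T2 = 1, T3 = 1, T4 = 1)
  )
  expect_equal(pred$mean_degree, 1.5)
  expect_identical(pred$key_targets, "T1")

  # all-equal degrees: nothing strictly exceeds the mean
  flat <- component_map(
    tibble::tibble(drug_id = "d1", metabolite_id = "m1"),
    tibble::tibble(metabolite_id = "m1", gene_symbol = c("T1", "T2"))
  )
  fnet <- build_network(ones_vector(drug_ids = "d1"), flat, character())
  expect_identical(select_key_targets(fnet)$key_targets, character(0))

  # averaging over all nodes is available as a sensitivity option
  pred_all <- select_key_targets(net, average = "all")
  expect_true(all(pred_all$key_targets %in% pred$degree_table$node))
})

test_that("dosage weighting can change the key-target set on one topology", {
  fx <- chong_he_fixture()
  dv <- standardize_dosage(fx$records)
  key_w <- select_key_targets(
    build_network(dv, fx$maps, fx$disease_targets)
  )$key_targets
  key_u <- select_key_targets(
    build_network(
      ones_vector(drug_ids = dv$drug_id), fx$maps, fx$disease_targets
    )
  )$key_targets
  expect_identical(key_u, c("G01", "G02"))
  expect_identical(key_w, c("G01", "G02", "G03", "G04", "G07"))
})

test_that("drug targets are the key targets found in the disease list", {
  pred <- structure(
    list(
      key_targets = c("A", "B", "C"), drug_targets = NULL,
      degree_table = tibble::tibble(), mean_degree = 0, average = "targets"
    ),
    class = "target_prediction"
  )
  expect_identical(
    intersect_disease_targets(pred, c("B", "C", "D"))$drug_targets,
    c("B", "C")
  )
  expect_identical(
    intersect_disease_targets(pred, "Z")$drug_targets, character(0)
  )
  expect_identical(
    intersect_disease_targets(pred, c("A", "B", "C", "X"))$drug_targets,
    pred$key_targets
  )
})

test_that("prediction sets are nested within the target layer", {
  for (b in small_ensemble(seed = 5, n = 5)) {
    net <- build_network(
      standardize_dosage(b$records), b$maps, b$disease_targets
    )
    pred <- intersect_disease_targets(
      select_key_targets(net), b$disease_targets
    )
    targets <- net$nodes$node[net$nodes$layer == "target"]
    expect_true(all(pred$drug_targets %in% pred$key_targets))
    expect_true(all(pred$key_targets %in% targets))
  }
})

test_that("networks round-trip through the edge-list TSV", {
  fx <- chong_he_fixture()
  net <- build_network(
    standardize_dosage(fx$records), fx$maps, fx$disease_targets
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, path)
  back <- read_network(path)
  expect_equal(back$edges, net$edges)
  expect_setequal(back$nodes$node, net$nodes$node)
})
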
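test_that("identical config and seed give identical annotations and ledgers", {
  a <- generate_organ_of_corti(small_config(), seed = 7)
  b <- generate_organ_of_corti(small_config(), seed = 7)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$ledger, b$ledger)
  c <- generate_organ_of_corti(small_config(), seed = 8)
  expect_false(identical(a$annotation, c$annotation))
})

test_that("the default census reproduces the reference cell counts and intact complexes", {
  sim <- generate_organ_of_corti(oc_config("cba1"), seed = 1)
  tt <- tree_table(sim$annotation)
  expect_equal(sum(tt$cell_class == "OHC"), 96)
  expect_equal(sum(tt$cell_class == "DC"), 96)
  expect_equal(sum(tt$cell_class == "OPC"), 32)
  expect_equal(sum(tt$cell_class == "T2SGN"), 40)
  expect_equal(sum(tt$cell_class == "MOC"), 70)
  led <- sim$ledger$complexes
  intact <- led[!led$dropped, ]
  expect_equal(as.vector(table(intact$row)), c(29, 30, 29))
})

test_that("generated annotations always pass structural validation", {
  for (seed in c(3, 14)) {
    sim <- generate_organ_of_corti(small_config(), seed = seed)
    expect_silent(validate_annotation(sim$annotation))
  }
})

test_that("ledger and annotation ids are bijective per entity class", {
  sim <- generate_organ_of_corti(small_config(), seed = 9)
  ids <- names(sim$annotation$trees)
  led <- sim$ledger
  expect_setequal(led$complexes$complex_id, ids[startsWith(ids, "DC")])
  expect_setequal(led$complexes$ohc_id, ids[startsWith(ids, "OHC")])
  expect_setequal(led$opcs$opc_id, ids[startsWith(ids, "OPC")])
  expect_setequal(led$fibers$fiber_id, ids[startsWith(ids, "T2SGN")])
  expect_setequal(led$moc$fiber_id, ids[startsWith(ids, "MOC")])
  # every contact resolves to ledgered entities
  expect_true(all(sim$annotation$contacts$fiber_id %in%
                    c(led$fibers$fiber_id, led$moc$fiber_id)))
})

test_that("sampled geometry honours the configured truncation and span rule", {
  sim <- generate_organ_of_corti(oc_config("cba1"), seed = 10,
                                 components = "lattice")
  led <- sim$ledger$complexes
  cfg <- sim$ledger$config$yshape
  for (r in 1:3) {
    lr <- led[led$row == r, ]
    expect_true(all(abs(lr$alpha - cfg$alpha$mean[r]) <=
                      4 * cfg$alpha$sd[r] + 1e-9))
    expect_true(all(abs(lr$L_OHC - cfg$L_OHC$mean[r]) <=
                      4 * cfg$L_OHC$sd[r] + 1e-9))
    expect_equal(unique(lr$span_target), cfg$span_rule[r])
  }
  expect_true(all(led$L_OHC > 0 & led$L_PhP > 0 & led$L_DC > 0))
})

test_that("generator config validation rejects broken settings", {
  expect_error(oc_config("cba1", list(t2sgn = list(mixing_prob = 1.5))),
               "probabilities")
  expect_error(oc_config("cba1", list(moc = list(
    unbranched_row_probs = c(0.5, 0.4, 0.2)))), "sum to 1")
  expect_error(oc_config("cba1", list(t2sgn = list(n_fibers = 11))),
               "row_split")
  expect_error(oc_config("no_such_preset"), class = "cortimorph_bad_input")
})

test_that("fiber ledger records turn nodes the analyzer can reproduce", {
  sim <- generate_organ_of_corti(oc_config("cba1"), seed = 6)
  ann <- sim$annotation
  frame <- build_reference_frame(ann, sim$ledger$basal_hint)
  band <- opc_radial_band(ann, frame)
  led <- sim$ledger$fibers
  hits <- 0
  for (i in seq_len(10)) {
    tr <- ann$trees[[led$fiber_id[i]]]
    tn <- locate_turn(tr, frame, radial_band = band)
    # same node up to the tangent-averaging window (5 um ~ 3 nodes)
    pos_t <- tr$nodes[match(tn, tr$nodes$node_id), c("x", "y", "z")]
    pos_l <- tr$nodes[match(led$turn_node[i], tr$nodes$node_id), c("x", "y", "z")]
    d <- sqrt(sum((pos_t - pos_l)^2)) / 1000
    if (d <= 5) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
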
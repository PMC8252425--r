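frame_xyz <- function() {
  # canonical frame: BM plane z = 0, rows along +x at y = 0, 7, 14 um
  rows <- lapply(1:3, function(r) {
    structure(list(row = r, point = c(0, (r - 1) * 7000, 0),
                   direction = c(1, 0, 0)), class = "oc_row_line")
  })
  structure(list(
    bm = structure(list(point = c(0, 0, 0), normal = c(0, 0, 1)),
                   class = "oc_plane"),
    rows = stats::setNames(rows, 1:3), basal_hint = c(1, 0, 0)),
    class = "oc_frame")
}

test_that("path length sums edges along the unique landmark path", {
  tr <- chain_tree("t", rbind(c(0, 0, 0), c(0, 0, 10000), c(0, 10000, 10000)),
                   landmarks = c(a = 1, b = 3))
  expect_equal(path_length(tr, "a", "b"), 20)
  expect_equal(path_length(tr, "a", "a"), 0)
  expect_error(path_length(tr, "a", "nope"), "nope",
               class = "cortimorph_missing_landmark")
})

test_that("path length dominates the straight-line landmark distance", {
  sim <- generate_organ_of_corti(small_config(), seed = 8, components = "lattice")
  for (tr in trees_of_class(sim$annotation, "DC")) {
    chord <- sqrt(sum((landmark_xyz(tr, "DC_root") -
                         landmark_xyz(tr, "PhP_branch_point"))^2)) / 1000
    expect_gte(path_length(tr, "DC_root", "PhP_branch_point") + 1e-9, chord)
  }
})

test_that("principal axis is the oriented first singular vector", {
  tr <- chain_tree("t", cbind(0, 0, seq(0, 20000, 2000)),
                   landmarks = c(base = 1, apex = 11))
  expect_equal(principal_axis(tr, "base", "apex"), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(principal_axis(tr, "apex", "base"), c(0, 0, -1), tolerance = 1e-12)
  same <- chain_tree("t", rbind(c(1, 1, 1), c(1, 1, 1)), landmarks = c(a = 1, b = 2))
  expect_error(principal_axis(same, "a", "b"), class = "cortimorph_degenerate")
})

test_that("intersection angle matches the closed form to 1e-9 degrees", {
  expect_equal(intersection_angle(c(0, 0, 1), c(0, sin(pi / 6), cos(pi / 6))),
               30, tolerance = 1e-9)
  expect_equal(intersection_angle(c(0, 0, 1), c(0, 0, 1)), 0, tolerance = 1e-9)
  set.seed(99)
  for (i in 1:25) {
    th <- runif(1, 0, pi)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    # rotate u by th within a random plane containing it
    w <- cortimorph:::pracma_cross(u, rnorm(3)); w <- w / sqrt(sum(w^2))
    v <- cos(th) * u + sin(th) * w
    expect_equal(intersection_angle(u, v), th * 180 / pi, tolerance = 1e-9)
  }
})

test_that("longitudinal angles against the fitted row line", {
  fr <- frame_xyz()
  expect_equal(unname(longitudinal_angle(c(1, 0, 0), fr, 1)["beta3d"]), 0,
               tolerance = 1e-9)
  b <- longitudinal_angle(c(0, 0, 1), fr, 2)
  expect_equal(unname(b["beta3d"]), 90, tolerance = 1e-9)
  expect_equal(unname(b["beta_proj"]), 90, tolerance = 1e-9)
  expect_error(longitudinal_angle(c(1, 0, 0), fr, 9), class = "cortimorph_bad_input")
})

test_that("a PhP inserting at its own column spans 1", {
  fr <- frame_xyz()
  # 5 OHC apices on row 1 at 6.5 um pitch
  ohcs <- lapply(1:5, function(j) {
    chain_tree(sprintf("OHC1_%03d", j),
               rbind(c((j - 1) * 6500, 0, 0), c((j - 1) * 6500, 0, 50000)),
               "OHC", 1L, landmarks = c(basal_pole = 1, cuticular_plate = 2))
  })
  dc <- chain_tree("DC1_003",
                   rbind(c(2 * 6500, 0, -30000), c(2 * 6500, 0, -1000),
                         c(2 * 6500, 500, 49000)),
                   "DC", 1L,
                   landmarks = c(DC_root = 1, PhP_branch_point = 2,
                                 PhP_apical_insertion = 3))
  ann <- oc_annotation(voxel_pitch(1, 1, 1), c(ohcs, list(dc)))
  lat <- rl_lattice(ann, fr)
  sp <- mosaic_span(dc, "OHC1_003", lat, fr)
  expect_equal(sp$span, 1L)
  expect_true("OHC1_003" %in% sp$partner_ids)
})

test_that("incomplete complexes are excluded and counted; empty annotation is fine", {
  sim <- generate_organ_of_corti(small_config(), seed = 4, components = "lattice")
  ann <- sim$annotation
  frame <- build_reference_frame(ann, sim$ledger$basal_hint)
  ys <- measure_yshapes(ann, frame)
  n_dropped <- sum(sim$ledger$complexes$dropped)
  expect_equal(nrow(ys$excluded), n_dropped)
  expect_equal(nrow(ys$measures),
               nrow(sim$ledger$complexes) - n_dropped)
  # knock out one OHC basal pole -> one more exclusion
  ohc1 <- ys$measures$ohc_id[1]
  ann2 <- ann
  ann2$trees[[ohc1]]$landmarks <-
    ann2$trees[[ohc1]]$landmarks[names(ann2$trees[[ohc1]]$landmarks) != "basal_pole"]
  ys2 <- measure_yshapes(ann2, frame)
  expect_equal(nrow(ys2$excluded), n_dropped + 2)  # OHC flagged + its DC unpaired
  expect_equal(nrow(ys2$measures), nrow(ys$measures) - 1)
  empty <- oc_annotation(voxel_pitch(), list())
  expect_equal(nrow(measure_yshapes(empty, frame)$measures), 0)
})

test_that("a noise-free lattice is recovered exactly up to voxel quantization", {
  cfg <- oc_config("cba1", modify_list_deep_test(
    list(lattice = list(n_columns = 8, dropout_basal = c(1, 1, 1))),
    noiseless_overrides()))
  sim <- generate_organ_of_corti(cfg, seed = 1, components = "lattice")
  frame <- build_reference_frame(sim$annotation, sim$ledger$basal_hint)
  ys <- measure_yshapes(sim$annotation, frame)
  led <- sim$ledger$complexes
  m <- merge(ys$measures, led, by = "complex_id", suffixes = c("", ".true"))
  expect_gt(nrow(m), 0)
  expect_lt(max(abs(m$L_OHC - m$L_OHC.true)), 0.05)       # um; quantization
  expect_lt(max(abs(m$alpha - m$alpha.true)), 0.2)        # degrees
  expect_lt(max(abs(m$beta_DC - m$beta_DC.true)), 0.2)
  expect_lt(max(abs(m$beta_OHC - m$beta_OHC.true)), 0.2)
  expect_equal(m$span, cfg$yshape$span_rule[m$row])
})

test_that("noisy generator axes stay within 1 degree of the ledger", {
  sim <- generate_organ_of_corti(oc_config("cba1"), seed = 12,
                                 components = "lattice")
  frame <- build_reference_frame(sim$annotation, sim$ledger$basal_hint)
  ys <- measure_yshapes(sim$annotation, frame)
  m <- merge(ys$measures, sim$ledger$complexes, by = "complex_id",
             suffixes = c("", ".true"))
  expect_lt(max(abs(m$alpha - m$alpha.true)), 1)
  expect_lt(max(abs(m$beta_DC - m$beta_DC.true)), 1)
})

test_that("beta_OHC - beta_PhP approximates alpha for near-planar complexes", {
  # a pitch of 8 um makes row-1 PhPs lie close to the longitudinal plane
  cfg <- oc_config("cba1", modify_list_deep_test(
    list(lattice = list(n_columns = 8, column_pitch_um = 8,
                        dropout_basal = c(1, 1, 1))),
    noiseless_overrides()))
  sim <- generate_organ_of_corti(cfg, seed = 1, components = "lattice")
  frame <- build_reference_frame(sim$annotation, sim$ledger$basal_hint)
  ys <- measure_yshapes(sim$annotation, frame)
  r1 <- ys$measures[ys$measures$row == 1, ]
  expect_true(all(r1$consistency_dev < 5))
  expect_false(any(r1$consistency_flag))
})
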
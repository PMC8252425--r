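test_that("total-least-squares plane fit matches analytic planes", {
  set.seed(1)
  pts <- cbind(runif(20, 0, 1e5), runif(20, 0, 1e5), 0)
  pl <- fit_bm_plane(pts)
  expect_equal(abs(pl$normal[3]), 1, tolerance = 1e-9)
  # plane z = x: normal proportional to (1, 0, -1)/sqrt(2)
  xy <- cbind(runif(20, 0, 1e5), runif(20, 0, 1e5))
  pts2 <- cbind(xy[, 1], xy[, 2], xy[, 1])
  pl2 <- fit_bm_plane(pts2)
  expect_equal(abs(sum(pl2$normal * c(1, 0, -1) / sqrt(2))), 1, tolerance = 1e-9)
  expect_error(fit_bm_plane(pts[1:2, ]), class = "cortimorph_degenerate")
  coll <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(fit_bm_plane(coll), "collinear", class = "cortimorph_degenerate")
})

test_that("plane fit is equivariant under rigid transforms", {
  set.seed(42)
  for (rep in 1:8) {
    pts <- cbind(runif(30, 0, 2e5), runif(30, 0, 1.4e4), rnorm(30, 0, 200))
    pl <- fit_bm_plane(pts)
    tf <- random_rigid()
    pl2 <- fit_bm_plane(apply_rigid(pts, tf))
    expect_lt(min(angle_deg(pl2$normal, tf$rot %*% pl$normal),
                  angle_deg(-pl2$normal, tf$rot %*% pl$normal)), 1e-6)
  }
})

test_that("row-line fit reproduces collinear points exactly and obeys the hint", {
  pts <- cbind(c(0, 1, 2), 0, 0)
  ln <- fit_row_line(pts, basal_hint = c(1, 0, 0))
  expect_equal(ln$direction, c(1, 0, 0), tolerance = 1e-12)
  ln2 <- fit_row_line(pts, basal_hint = c(-1, 0, 0))
  expect_equal(ln2$direction, c(-1, 0, 0), tolerance = 1e-12)
  expect_error(fit_row_line(cbind(c(1, 1), c(2, 2), c(3, 3)), c(1, 0, 0)),
               class = "cortimorph_degenerate")
})

test_that("heights above the BM are signed perpendicular distances in um", {
  pl <- structure(list(point = c(0, 0, 0), normal = c(0, 0, 1)),
                  class = "oc_plane")
  expect_equal(height_above_bm(c(0, 0, 5000), pl), 5)
  expect_equal(height_above_bm(c(123, -77, 0), pl), 0)
  expect_lt(height_above_bm(c(0, 0, -2000), pl), 0)
})

test_that("frame fitted on generator output recovers plane and rows within 1 degree", {
  for (seed in c(2, 7)) {
    sim <- generate_organ_of_corti(oc_config("cba1"), seed = seed,
                                   components = "lattice")
    frame <- build_reference_frame(sim$annotation, sim$ledger$basal_hint)
    expect_lt(angle_deg(frame$bm$normal, sim$ledger$bm_normal), 1)
    for (r in 1:3) {
      expect_lt(angle_deg(frame$rows[[as.character(r)]]$direction,
                          sim$ledger$row_direction), 1)
    }
  }
})

test_that("reference frames survive JSON serialization", {
  sim <- generate_organ_of_corti(small_config(), seed = 5, components = "lattice")
  frame <- build_reference_frame(sim$annotation, sim$ledger$basal_hint)
  f <- tempfile(fileext = ".json")
  frame_to_json(frame, f)
  back <- frame_from_json(f)
  expect_equal(back$bm$normal, frame$bm$normal, tolerance = 1e-12)
  expect_equal(back$rows[[2]]$direction, frame$rows[[2]]$direction,
               tolerance = 1e-12)
  expect_equal(back$basal_hint, frame$basal_hint, tolerance = 1e-12)
})
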
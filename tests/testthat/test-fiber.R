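mini_frame <- function() {
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

test_that("the turn is the sharpest windowed bend; straight fibers have none", {
  inb <- cbind(0, seq(-30000, 0, 2000), 10000)
  outb <- cbind(seq(2000, 40000, 2000), 0, 10000)
  fib <- chain_tree("T2SGN_x", rbind(inb, outb), "T2SGN")
  tn <- locate_turn(fib, mini_frame())
  bend_index <- nrow(inb)
  expect_lte(abs(tn - bend_index), 1)
  straight <- chain_tree("s", cbind(seq(0, 60000, 2000), 0, 10000), "T2SGN")
  expect_true(is.na(locate_turn(straight, mini_frame())))
})

test_that("profile samples attach to supports within the radius only", {
  fr <- mini_frame()
  # one vertical DC trunk at x = 20 um, row 1
  dc <- chain_tree("DC1_001",
                   rbind(c(20000, 0, 0), c(20000, 0, 30000), c(20000, 3000, 50000)),
                   "DC", 1L,
                   landmarks = c(DC_root = 1, PhP_branch_point = 2,
                                 PhP_apical_insertion = 3))
  # fiber turns at x 0 (90-degree bend), runs basally, passes the trunk at
  # 1 um radial offset (attached), then a later stretch at 3 um (not attached)
  inb <- cbind(0, seq(-26000, -6000, 2000), 15000)
  xo <- seq(2000, 40000, 2000)
  yo <- ifelse(xo <= 8000, -6000,
               ifelse(xo <= 14000, -6000 + (xo - 8000) * 7 / 6,
                      ifelse(xo <= 28000, 1000, 3000)))
  outb <- cbind(xo, yo, 15000)
  fib <- chain_tree("T2SGN_001", rbind(inb, outb), "T2SGN")
  ann <- oc_annotation(voxel_pitch(1, 1, 1), list(dc, fib))
  pr <- build_profile(fib, ann, fr, attach_radius_um = 2)
  s <- pr$samples
  near <- s[abs(s$node_id - 0) > 0 & !is.na(s$support_id), ]
  expect_true(all(near$support_id == "DC1_001"))
  # the node nearest the trunk is attached; nodes 3 um off radially are not
  expect_true(any(!is.na(s$support_id)))
  far <- s[s$longitudinal_um > 32, ]
  expect_true(all(is.na(far$support_id)))
  expect_true(all(abs(s$height_um - 15) < 0.01))
})

test_that("biphasic OLS recovers noiseless piecewise slopes exactly", {
  lon <- seq(0, 40, 1)
  bp <- 21
  h <- ifelse(seq_along(lon) <= bp, 5 + 0.25 * lon, 5 + 0.25 * lon[bp] +
                0 * (lon - lon[bp]))
  prof <- structure(list(
    fiber_id = "f",
    samples = tibble::tibble(node_id = seq_along(lon), arc_um = lon,
                             longitudinal_um = lon, height_um = h,
                             support_id = NA_character_,
                             support_class = NA_character_,
                             is_collateral_origin = seq_along(lon) == bp),
    turn_node = 1L), class = "fiber_profile")
  fit <- fit_biphasic(prof, dc_pitch_um = 6.8)
  expect_equal(fit$climbing_slope, 0.25, tolerance = 1e-9)
  expect_equal(fit$contact_slope, 0, tolerance = 1e-9)
  expect_equal(fit$climbing_slope_per_dc, 0.25 * 6.8, tolerance = 1e-9)
  td <- tidy(fit)
  expect_equal(td$slope, c(0.25, 0))
  expect_equal(glance(fit)$breakpoint_index, bp)
  # no collateral: climbing reported, contact undefined
  prof$samples$is_collateral_origin <- FALSE
  fit2 <- fit_biphasic(prof)
  expect_true(is.na(fit2$contact_slope))
  expect_false(is.na(fit2$climbing_slope))
})

test_that("contact-height groups report means, with empty groups at n = 0", {
  rs <- tibble::tibble(
    fiber_id = "f1", node_id = 1:3, arc_um = 1:3, longitudinal_um = 1:3,
    height_um = c(10, 10, 22), support_id = c("DC2_004", "DC2_004", NA),
    support_class = c("DC2", "DC2", NA), is_collateral_origin = FALSE,
    region = c("climbing", "climbing", "contact"))
  hs <- contact_height_stats(rs)
  expect_equal(hs$mean[hs$group == "DC2"], 10)
  expect_equal(hs$n[hs$group == "DC2"], 1)  # one (fiber, support) site
  expect_equal(hs$n[hs$group == "OPC"], 0)
  expect_equal(hs$n[hs$group == "OHC_contact"], 0)
})

test_that("innervation matrices conserve contact counts", {
  sim <- generate_organ_of_corti(oc_config("cba1"), seed = 2)
  ann <- sim$annotation
  aff <- innervation_matrix(ann, "afferent")
  eff <- innervation_matrix(ann, "efferent")
  n_aff <- sum(ann$contacts$bouton_class %in%
                 c("afferent_ribbon", "afferent_ribbonless"))
  n_eff <- sum(ann$contacts$bouton_class == "efferent")
  expect_equal(sum(aff$counts), n_aff)
  expect_equal(sum(eff$counts), n_eff)
  # per-fiber marginals match the contact table
  tab <- table(ann$contacts$fiber_id[ann$contacts$bouton_class != "efferent"])
  expect_equal(unname(rowSums(aff$counts)[names(tab)]), as.vector(tab))
  ac <- afferent_counts(aff)
  expect_equal(sum(ac$per_ohc$n_contacts), n_aff)
  expect_true(all(ac$per_row$ribbon_fraction >= 0 &
                    ac$per_row$ribbon_fraction <= 1))
})

test_that("row specificity flags exclusive fibers and modal fractions", {
  counts <- rbind(
    f1 = c(OHC2_001 = 2L, OHC2_002 = 1L, OHC1_001 = 0L),
    f2 = c(OHC2_001 = 1L, OHC2_002 = 0L, OHC1_001 = 1L),
    f3 = c(OHC2_001 = 0L, OHC2_002 = 0L, OHC1_001 = 0L))
  imat <- structure(list(
    counts = counts,
    long = tibble::tibble(),
    target_rows = c(OHC2_001 = 2L, OHC2_002 = 2L, OHC1_001 = 1L),
    kind = "afferent"), class = "innervation_matrix")
  rs <- row_specificity(imat)
  pf <- rs$per_fiber
  expect_true(pf$exclusive[pf$fiber_id == "f1"])
  expect_equal(pf$modal_fraction[pf$fiber_id == "f1"], 1)
  expect_false(pf$exclusive[pf$fiber_id == "f2"])
  expect_equal(pf$modal_fraction[pf$fiber_id == "f2"], 0.5)
  expect_equal(rs$n_zero_contact, 1)
  expect_equal(rs$exclusive_fraction, 0.5)
})

test_that("zero mixing probability gives fully row-exclusive fibers", {
  cfg <- small_config(list(t2sgn = list(mixing_prob = 0)))
  sim <- generate_organ_of_corti(cfg, seed = 21)
  rs <- row_specificity(innervation_matrix(sim$annotation, "afferent"))
  expect_equal(rs$exclusive_fraction, 1)
})
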
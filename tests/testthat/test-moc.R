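zone_y <- function() tc_zone(c(0, -14000, 0), c(0, 1, 0), 4)

test_that("single and double slab traversals classify as expected", {
  single <- chain_tree("MOC_001",
                       cbind(0, seq(-30000, 0, 2000), 10000), "MOC")
  got <- classify_moc(single, zone_y(), n_synapses = 3L)
  expect_equal(got$n_tunnel_crossings, 1L)
  expect_equal(got$subtype, "unbranched")
  # bifurcation before the slab, both branches crossing
  stem <- cbind(0, seq(-30000, -18000, 2000), 10000)
  brA <- cbind(-8000, seq(-16000, 0, 2000), 10000)
  brB <- cbind(8000, seq(-16000, 0, 2000), 10000)
  xyz <- rbind(stem, brA, brB)
  n_stem <- nrow(stem); nA <- nrow(brA)
  nodes <- tibble::tibble(node_id = seq_len(nrow(xyz)), x = xyz[, 1],
                          y = xyz[, 2], z = xyz[, 3], radius = NA_real_)
  edges <- tibble::tibble(
    from = c(seq_len(n_stem - 1), n_stem, n_stem + seq_len(nA - 1),
             n_stem, n_stem + nA + seq_len(nA - 1)),
    to = c(2:n_stem, n_stem + 1, n_stem + 1 + seq_len(nA - 1),
           n_stem + nA + 1, n_stem + nA + 1 + seq_len(nA - 1)))
  forked <- skeleton_tree("MOC_002", "MOC", NA, nodes, edges)
  got2 <- classify_moc(forked, zone_y())
  expect_equal(got2$n_tunnel_crossings, 2L)
  expect_equal(got2$subtype, "branched")
  # never entering the slab
  outside <- chain_tree("MOC_003", cbind(seq(0, 20000, 2000), 0, 10000), "MOC")
  expect_error(classify_moc(outside, zone_y()), class = "cortimorph_not_moc")
})

test_that("crossing counts are invariant to edge subdivision", {
  sim <- generate_organ_of_corti(small_config(), seed = 13)
  zone <- sim$tc_zone
  mocs <- trees_of_class(sim$annotation, "MOC")
  for (tr in mocs[1:4]) {
    base <- classify_moc(tr, zone)$n_tunnel_crossings
    # subdivide every edge at its midpoint
    nd <- tr$nodes
    ed <- tr$edges
    mid_id <- max(nd$node_id) + seq_len(nrow(ed))
    a <- nd[match(ed$from, nd$node_id), ]
    b <- nd[match(ed$to, nd$node_id), ]
    mids <- tibble::tibble(node_id = mid_id, x = (a$x + b$x) / 2,
                           y = (a$y + b$y) / 2, z = (a$z + b$z) / 2,
                           radius = NA_real_)
    new_edges <- tibble::tibble(
      from = c(ed$from, mid_id), to = c(mid_id, ed$to))
    sub <- skeleton_tree(tr$tree_id, "MOC", NA,
                         dplyr::bind_rows(nd, mids), new_edges, tr$landmarks)
    expect_equal(classify_moc(sub, zone)$n_tunnel_crossings, base)
  }
})

test_that("population classification matches the generator's subtype ledger", {
  sim <- generate_organ_of_corti(oc_config("cba1"), seed = 5,
                                 components = c("lattice", "moc"))
  cls <- classify_moc_all(sim$annotation, sim$tc_zone)
  led <- sim$ledger$moc
  m <- merge(cls, led, by = "fiber_id")
  expect_false(any(m$flagged))
  expect_equal(m$subtype == "branched", m$branched)
  expect_equal(m$n_tunnel_crossings, m$n_crossings)
  expect_equal(m$n_synapses.x, m$n_synapses.y)
  expect_equal(sum(m$subtype == "branched"), 17)
})

test_that("a fully branched configuration yields >= 2 crossings everywhere", {
  cfg <- small_config(list(moc = list(branched_fraction = 1)))
  sim <- generate_organ_of_corti(cfg, seed = 6, components = c("lattice", "moc"))
  cls <- classify_moc_all(sim$annotation, sim$tc_zone)
  expect_true(all(cls$n_tunnel_crossings >= 2))
})

test_that("efferent summaries count boutons per OHC and per subtype", {
  sim <- generate_organ_of_corti(oc_config("cba1"), seed = 4,
                                 components = c("lattice", "moc"))
  ann <- sim$annotation
  imat <- innervation_matrix(ann, "efferent")
  cls <- classify_moc_all(ann, sim$tc_zone)
  ef <- efferent_counts(imat, cls)
  expect_equal(sum(ef$per_ohc$n_contacts), sum(imat$counts))
  expect_equal(sum(ef$per_subtype$n_fibers), nrow(cls))
  expect_true(all(ef$per_subtype$min >= 1))
  shares <- ef$row_shares
  for (st in c("branched", "unbranched")) {
    expect_equal(sum(shares$share_pct[shares$subtype == st]), 100,
                 tolerance = 1e-9)
  }
  # subtype synapse ranges respect the configured truncation
  bs <- ef$per_subtype[ef$per_subtype$subtype == "branched", ]
  us <- ef$per_subtype[ef$per_subtype$subtype == "unbranched", ]
  expect_gte(bs$min, 3); expect_lte(bs$max, 11)
  expect_gte(us$min, 1); expect_lte(us$max, 4)
})

test_that("discrete synapse-count calibration hits the printed means", {
  tb <- cortimorph:::calibrate_discrete_gaussian(5.18, 2.30, 3, 11)
  expect_equal(sum(tb$k * tb$p), 5.18, tolerance = 1e-8)
  expect_true(all(tb$k == 3:11))
  tu <- cortimorph:::calibrate_discrete_gaussian(2.26, 1.00, 1, 4)
  expect_equal(sum(tu$k * tu$p), 2.26, tolerance = 1e-8)
})
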
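test_that("tree name grammar parses class and row", {
  got <- parse_tree_name(c("OHC2_017", "MOC_007", "DC3_012", "weird"))
  expect_equal(got$cell_class, c("OHC", "MOC", "DC", NA))
  expect_equal(got$row, c(2L, NA, 3L, NA))
})

test_that("NML voxel coordinates scale by the pitch and parsing is pitch-linear", {
  nml <- tempfile(fileext = ".nml")
  writeLines(c(
    '<things>',
    ' <thing id="1" name="OHC1_001">',
    '  <nodes><node id="1" x="0" y="0" z="0"/><node id="2" x="0" y="0" z="100"/></nodes>',
    '  <edges><edge source="1" target="2"/></edges>',
    '  <comments><comment node="1" content="landmark:basal_pole"/>',
    '            <comment node="2" content="landmark:cuticular_plate"/></comments>',
    ' </thing>',
    '</things>'), nml)
  ann <- read_nml(nml, voxel_pitch(11, 11, 40))
  tr <- ann$trees[[1]]
  expect_equal(tr$cell_class, "OHC")
  expect_equal(tr$row, 1L)
  expect_equal(path_length(tr, "basal_pole", "cuticular_plate"), 4)  # 100 * 40 nm
  ann2 <- read_nml(nml, voxel_pitch(22, 22, 80))
  expect_equal(path_length(ann2$trees[[1]], "basal_pole", "cuticular_plate"), 8)
})

test_that("validation rejects dangling edges, duplicate ids and non-tree graphs", {
  nodes <- tibble::tibble(node_id = 1:2, x = c(0, 1), y = 0, z = 0, radius = NA_real_)
  expect_error(
    validate_tree(skeleton_tree("t", "MOC", NA, nodes,
                                tibble::tibble(from = 1L, to = 99L))),
    "99", class = "cortimorph_validation")
  dup <- tibble::tibble(node_id = c(1L, 1L), x = 0, y = 0, z = 0, radius = NA_real_)
  expect_error(validate_tree(skeleton_tree("t", "MOC", NA, dup,
                                           tibble::tibble(from = integer(), to = integer()))),
               "duplicate", class = "cortimorph_validation")
  # randomized corrupted fixtures: an added edge creates a cycle, a removed
  # edge disconnects; both must be rejected
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(5:12, 1)
    xyz <- matrix(rnorm(3 * n, 0, 1000), ncol = 3)
    tr <- chain_tree("t", xyz, "MOC")
    extra <- sort(sample(n, 2))
    cyc <- tr
    cyc$edges <- dplyr::bind_rows(cyc$edges,
                                  tibble::tibble(from = extra[1], to = extra[2]))
    expect_error(validate_tree(cyc), class = "cortimorph_validation")
    cut <- tr
    cut$edges <- cut$edges[-sample(n - 1, 1), ]
    expect_error(validate_tree(cut), class = "cortimorph_validation")
  }
})

test_that("SWC reading: edges from parents, root landmark, cycle detection", {
  swc <- tempfile(fileext = ".swc")
  writeLines(c("# test", "1 0 0 0 0 1 -1", "2 0 0 0 5 1 1", "3 0 0 0 10 1 2"), swc)
  ann <- read_swc(swc, voxel_pitch(1, 1, 1),
                  labels = tibble::tibble(path = swc, cell_class = "MOC", row = NA))
  tr <- ann$trees[[1]]
  expect_equal(nrow(tr$edges), 2)
  expect_equal(unname(tr$landmarks[["root"]]), 1L)
  bad <- tempfile(fileext = ".swc")
  writeLines(c("1 0 0 0 0 1 2", "2 0 0 0 5 1 1"), bad)
  expect_error(read_swc(bad, voxel_pitch(1, 1, 1),
                        labels = tibble::tibble(path = bad, cell_class = "MOC", row = NA)),
               "cyclic", class = "cortimorph_validation")
})

test_that("round trips preserve topology and labels, positions to half a voxel", {
  sim <- generate_organ_of_corti(small_config(), seed = 11)
  ann <- sim$annotation
  f <- tempfile(fileext = ".nml")
  write_annotation(ann, f, "nml")
  back <- suppressWarnings(read_nml(f, ann$pitch))
  expect_setequal(names(back$trees), names(ann$trees))
  for (id in names(ann$trees)) {
    a <- ann$trees[[id]]; b <- back$trees[[id]]
    expect_equal(b$cell_class, a$cell_class)
    expect_equal(b$row, a$row)
    expect_equal(nrow(b$edges), nrow(a$edges))
    expect_equal(sort(names(b$landmarks)), sort(names(a$landmarks)))
    expect_lt(max(abs(node_xyz(b) - node_xyz(a))), max(ann$pitch) / 2 + 1e-9)
  }
  # contacts csv round trip
  fc <- tempfile(fileext = ".csv")
  write_annotation(ann, fc, "contacts-csv")
  stripped <- ann
  stripped$contacts <- cortimorph:::empty_contacts()
  back2 <- read_contacts(fc, stripped)
  expect_equal(nrow(back2$contacts), nrow(ann$contacts))
  expect_equal(back2$contacts$fiber_id, ann$contacts$fiber_id)
  expect_equal(back2$contacts$bouton_class, ann$contacts$bouton_class)
  # swc round trip for one tree
  d <- tempfile()
  write_annotation(ann, d, "swc")
  expect_true(length(list.files(d, pattern = "\\.swc$")) == length(ann$trees))
  expect_error(write_annotation(ann, tempfile(), "foo"),
               "unsupported", class = "cortimorph_bad_input")
})

test_that("contact tables validate fiber/target classes", {
  sim <- generate_organ_of_corti(small_config(), seed = 3)
  ann <- sim$annotation
  t2 <- names(trees_of_class(ann, "T2SGN"))[1]
  ohc <- names(trees_of_class(ann, "OHC"))[1]
  f <- tempfile(fileext = ".csv")
  writeLines(c("fiber_id,target_id,bouton_class,x,y,z,node_id",
               sprintf("%s,%s,efferent,0,0,0,1", t2, ohc)), f)
  expect_error(read_contacts(f, ann), "inconsistent",
               class = "cortimorph_validation")
  writeLines(c("fiber_id,target_id,bouton_class,x,y,z,node_id",
               sprintf("ghost,%s,afferent_ribbon,0,0,0,1", ohc)), f)
  expect_error(read_contacts(f, ann), "ghost", class = "cortimorph_validation")
  writeLines("fiber_id,target_id,bouton_class,x,y,z,node_id", f)
  expect_warning(out <- read_contacts(f, ann), "empty")
  expect_equal(nrow(out$contacts), nrow(ann$contacts))
})
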
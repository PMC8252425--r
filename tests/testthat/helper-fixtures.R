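# Small in-code fixtures shared across the suite.

# unbranched tree through the given positions (nm), optional named landmarks
# as node indices into the chain
chain_tree <- function(id, xyz, cell_class = NA_character_, row = NA_integer_,
                       landmarks = integer()) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  nodes <- tibble::tibble(node_id = seq_len(n), x = xyz[, 1], y = xyz[, 2],
                          z = xyz[, 3], radius = NA_real_)
  edges <- tibble::tibble(from = seq_len(n - 1), to = 2:n)
  lm <- stats::setNames(as.integer(landmarks), names(landmarks))
  skeleton_tree(id, cell_class, row, nodes, edges, lm)
}

um <- function(x) x * 1000  # um -> nm

# small, fast generator configuration (8 columns, 6 fibers, 6 MOCs)
small_config <- function(overrides = list()) {
  base <- list(
    lattice = list(n_columns = 8, dropout_basal = c(1, 1, 1)),
    t2sgn = list(n_fibers = 6, row_split = c(2, 2, 2),
                 dc_abundance = list(mean = c(3, 2, 1), sd = c(0.5, 0.5, 0.5)),
                 quota_columns = c(2, 6), census_columns = c(4, 6),
                 breakpoint_columns = c(1, 4)),
    moc = list(n_fibers = 6)
  )
  oc_config("cba1", modify_list_deep_test(base, overrides))
}

modify_list_deep_test <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list_deep_test(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

# noise-free configuration: all SDs and jitters zero (voxel quantization only)
noiseless_overrides <- function() {
  zero3 <- list(sd = c(0, 0, 0))
  list(
    lattice = list(bow_sd_nm = 0, node_sd_nm = 0, root_z_sd_nm = 0,
                   root_xy_sd_nm = 0, apex_x_sd_nm = 0),
    yshape = list(L_OHC = zero3, L_PhP = zero3, L_DC = zero3,
                  alpha = zero3, beta_DC = zero3, beta_OHC = zero3,
                  beta_OPC = list(sd = 0), L_OPC = list(sd = 0))
  )
}

# random rigid transform (rotation + translation), seeded by caller
random_rigid <- function() {
  m <- matrix(rnorm(9), 3)
  qr_r <- qr(m)
  rot <- qr.Q(qr_r)
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  list(rot = rot, shift = rnorm(3, 0, 5000))
}

apply_rigid <- function(pts, tf) {
  sweep(as.matrix(pts) %*% t(tf$rot), 2, -tf$shift)
}
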
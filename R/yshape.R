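#' Path length between two landmarks, in micrometres
#'
#' Sum of Euclidean edge lengths along the unique tree path between the two
#' landmark nodes.
#'
#' @param tree a [skeleton_tree()].
#' @param from,to landmark names.
#' @return length in um (0 when `from == to`).
#' @export
path_length <- function(tree, from, to) {
  ids <- path_node_ids(tree, from, to)
  if (length(ids) < 2) return(0)
  xyz <- node_xyz(tree)[match(ids, tree$nodes$node_id), , drop = FALSE]
  sum(sqrt(rowSums(diff(xyz)^2))) / NM_PER_UM
}

#' @keywords internal
path_node_ids <- function(tree, from, to) {
  for (lm in c(from, to)) {
    if (!lm %in% names(tree$landmarks)) {
      abort(sprintf("tree %s: landmark '%s' missing", tree$tree_id, lm),
            class = "cortimorph_missing_landmark")
    }
  }
  a <- as.character(tree$landmarks[[from]])
  b <- as.character(tree$landmarks[[to]])
  if (identical(a, b)) return(as.integer(a))
  g <- tree_graph(tree)
  sp <- igraph::shortest_paths(g, from = a, to = b)$vpath[[1]]
  as.integer(igraph::V(g)$name[as.integer(sp)])
}

#' Principal axis of a landmark-to-landmark path
#'
#' First right-singular vector of the centred path-node coordinates, oriented
#' from the `from` landmark toward the `to` landmark (positive projection on
#' the chord). Whole-structure vectorization: all nodes on the path enter the
#' SVD, not just the endpoints.
#'
#' @inheritParams path_length
#' @return unit 3-vector.
#' @export
principal_axis <- function(tree, from, to) {
  ids <- path_node_ids(tree, from, to)
  xyz <- node_xyz(tree)[match(ids, tree$nodes$node_id), , drop = FALSE]
  if (nrow(xyz) < 2 || max(abs(sweep(xyz, 2, colMeans(xyz)))) < 1e-12) {
    abort(sprintf("tree %s: degenerate path (%s -> %s), nodes coincide",
                  tree$tree_id, from, to), class = "cortimorph_degenerate")
  }
  sv <- svd(sweep(xyz, 2, colMeans(xyz)))
  ax <- sv$v[, 1]
  chord <- xyz[nrow(xyz), ] - xyz[1, ]
  if (sum(ax * chord) < 0) ax <- -ax
  unitize(ax, tol = 1e-9)
}

#' Intersection angle between co-oriented axes, in degrees
#'
#' The Y-shape opening angle alpha between the OHC axis and the PhP axis of
#' one complex. Both axes must be oriented BM -> RL; the angle is the plain
#' arccos of the dot product, not folded to <= 90 degrees, so a straight
#' continuation reads 0.
#'
#' @param axis_a,axis_b unit 3-vectors, both oriented BM -> RL.
#' @return angle in degrees, in `[0, 180]`.
#' @export
intersection_angle <- function(axis_a, axis_b) {
  angle_deg(unitize(axis_a), unitize(axis_b))
}

#' Longitudinal angle of an axis against its row line
#'
#' `beta3d` is the full 3D angle between the axis and the (basally oriented)
#' fitted row direction. `beta_proj` first projects the axis into the
#' longitudinal plane spanned by the row direction and the BM normal, then
#' measures the same angle; it discards radial tilt. `beta3d` is the headline
#' value.
#'
#' @param axis unit 3-vector oriented BM -> RL.
#' @param frame an `oc_frame` from [build_reference_frame()].
#' @param row which row's line to use (OPCs use row 1, the row they abut).
#' @return named numeric `c(beta3d = , beta_proj = )`, degrees.
#' @export
longitudinal_angle <- function(axis, frame, row) {
  key <- as.character(row)
  if (!key %in% names(frame$rows)) {
    abort(sprintf("row %s absent from reference frame", row),
          class = "cortimorph_bad_input")
  }
  axis <- unitize(axis)
  d <- frame$rows[[key]]$direction
  nrm <- frame$bm$normal
  beta3d <- angle_deg(axis, d)
  lateral <- unitize(pracma_cross(d, nrm), tol = 1)
  proj <- axis - sum(axis * lateral) * lateral
  beta_proj <- if (sqrt(sum(proj^2)) < 1e-9) NA_real_ else angle_deg(proj, d)
  c(beta3d = beta3d, beta_proj = beta_proj)
}

#' @keywords internal
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Reticular-lamina lattice of OHC apical landmarks
#'
#' One row per OHC with a cuticular-plate landmark: position, row, and column
#' rank from projecting the apices of each row onto that row's fitted line
#' (rank increases toward the base).
#'
#' @param ann an [oc_annotation()].
#' @param frame an `oc_frame`.
#' @return tibble `tree_id, row, x, y, z, s` (projection, nm), `column`.
#' @export
rl_lattice <- function(ann, frame) {
  ohcs <- keep(trees_of_class(ann, "OHC"),
               ~ "cuticular_plate" %in% names(.x$landmarks))
  if (length(ohcs) == 0) {
    return(tibble(tree_id = character(), row = integer(), x = double(),
                  y = double(), z = double(), s = double(), column = integer()))
  }
  pos <- t(vapply(ohcs, landmark_xyz, numeric(3), landmark = "cuticular_plate"))
  lat <- tibble(tree_id = map_chr(ohcs, "tree_id"),
                row = map_int(ohcs, "row"),
                x = pos[, 1], y = pos[, 2], z = pos[, 3])
  lat <- lat |>
    group_by(row) |>
    mutate(s = {
      ln <- frame$rows[[as.character(row[1])]]
      drop(sweep(cbind(x, y, z), 2, ln$point) %*% ln$direction)
    }) |>
    mutate(column = rank(.data$s, ties.method = "first")) |>
    ungroup()
  lat
}

#' Mosaic span of one phalangeal process
#'
#' Number of OHC columns, inclusive, between the complex's own OHC apex column
#' and the RL column nearest the PhP apical insertion, counted in the PhP's
#' own row's column indexing. The mosaic rule of the three-row lattice predicts spans 4/3/2 for
#' rows 1/2/3. Near-ties between neighbouring columns are broken toward the
#' base and flagged.
#'
#' @param dc_tree a DC [skeleton_tree()] with a `PhP_apical_insertion` landmark.
#' @param own_ohc_id tree id of the complex's own OHC in `lattice`.
#' @param lattice an [rl_lattice()].
#' @param frame an `oc_frame`.
#' @param neighborhood_um radius for collecting abutting partner OHC apices
#'   (default 6 um).
#' @param tie_tol_um near-tie width triggering the basal tie-break flag.
#' @return list `span`, `partner_ids`, `tie_flag`.
#' @export
mosaic_span <- function(dc_tree, own_ohc_id, lattice, frame,
                        neighborhood_um = 6, tie_tol_um = 0.05) {
  ins <- landmark_xyz(dc_tree, "PhP_apical_insertion")
  row <- dc_tree$row
  rowlat <- lattice[lattice$row == row, ]
  own <- rowlat[rowlat$tree_id == own_ohc_id, ]
  if (nrow(own) == 0) {
    abort(sprintf("own OHC '%s' not in the RL lattice of row %d", own_ohc_id, row),
          class = "cortimorph_bad_input")
  }
  ln <- frame$rows[[as.character(row)]]
  s_ins <- sum((ins - ln$point) * ln$direction)
  dists <- abs(rowlat$s - s_ins)
  o <- order(dists)
  tie_flag <- FALSE
  best <- o[1]
  if (length(o) > 1 && abs(dists[o[1]] - dists[o[2]]) < tie_tol_um * NM_PER_UM) {
    # deterministic tie-break toward the base (larger projection)
    cand <- o[1:2]
    best <- cand[which.max(rowlat$s[cand])]
    tie_flag <- TRUE
  }
  span <- abs(rowlat$column[best] - own$column[1]) + 1L
  all_d <- sqrt((lattice$x - ins[1])^2 + (lattice$y - ins[2])^2 +
                  (lattice$z - ins[3])^2)
  partners <- lattice$tree_id[all_d <= neighborhood_um * NM_PER_UM]
  list(span = as.integer(span), partner_ids = partners, tie_flag = tie_flag)
}

#' Measure every Y-shaped OHC-DC complex
#'
#' Pairs each landmarked DC with the OHC whose basal pole is nearest its PhP
#' branch point (the DC cup), then measures lengths, SVD axes, the
#' intersection angle alpha, longitudinal angles beta, and the mosaic span.
#' Complexes with missing landmarks are excluded and counted, mirroring the
#' intact-complex census (only complete Y-shapes are quantified).
#'
#' @param ann an [oc_annotation()].
#' @param frame an `oc_frame`.
#' @param pair_radius_um maximum cup-to-basal-pole pairing distance (default
#'   3 um).
#' @param consistency_tol_deg tolerance for the geometric consistency flag
#'   `|(beta_OHC - beta_PhP) - alpha| <= tol` (default 5 degrees; violations
#'   are flagged, not fatal).
#' @return list of class `oc_yshapes`: `measures` (tibble, one complex per
#'   row), `excluded` (tibble with reasons), `lattice`.
#' @export
measure_yshapes <- function(ann, frame, pair_radius_um = 3,
                            consistency_tol_deg = 5) {
  dcs <- trees_of_class(ann, "DC")
  ohcs <- trees_of_class(ann, "OHC")
  lattice <- rl_lattice(ann, frame)
  excl <- list()
  note_excl <- function(id, reason) {
    excl[[length(excl) + 1]] <<- tibble(tree_id = id, reason = reason)
  }
  ohc_ok <- keep(ohcs, ~ all(c("basal_pole", "cuticular_plate") %in%
                               names(.x$landmarks)))
  for (tr in ohcs) {
    if (!tr$tree_id %in% map_chr(ohc_ok, "tree_id")) {
      note_excl(tr$tree_id, "OHC missing basal_pole/cuticular_plate landmark")
    }
  }
  bases <- if (length(ohc_ok) > 0) {
    t(vapply(ohc_ok, landmark_xyz, numeric(3), landmark = "basal_pole"))
  } else matrix(numeric(), ncol = 3)
  rows_out <- list()
  for (dc in dcs) {
    need <- c("DC_root", "PhP_branch_point", "PhP_apical_insertion")
    if (!all(need %in% names(dc$landmarks))) {
      note_excl(dc$tree_id, "DC missing landmark(s)")
      next
    }
    cup <- landmark_xyz(dc, "PhP_branch_point")
    if (nrow(bases) == 0) {
      note_excl(dc$tree_id, "no landmarked OHC to pair")
      next
    }
    d <- sqrt(rowSums(sweep(bases, 2, cup)^2))
    j <- which.min(d)
    if (d[j] > pair_radius_um * NM_PER_UM) {
      note_excl(dc$tree_id, "no OHC basal pole within pairing radius")
      next
    }
    ohc <- ohc_ok[[j]]
    if (!identical(ohc$row, dc$row)) {
      note_excl(dc$tree_id, "paired OHC row disagrees with DC row")
      next
    }
    l_ohc <- path_length(ohc, "basal_pole", "cuticular_plate")
    l_php <- path_length(dc, "PhP_branch_point", "PhP_apical_insertion")
    l_dc <- path_length(dc, "DC_root", "PhP_branch_point")
    ax_ohc <- principal_axis(ohc, "basal_pole", "cuticular_plate")
    ax_php <- principal_axis(dc, "PhP_branch_point", "PhP_apical_insertion")
    ax_dc <- principal_axis(dc, "DC_root", "PhP_branch_point")
    alpha <- intersection_angle(ax_ohc, ax_php)
    b_ohc <- longitudinal_angle(ax_ohc, frame, dc$row)
    b_php <- longitudinal_angle(ax_php, frame, dc$row)
    b_dc <- longitudinal_angle(ax_dc, frame, dc$row)
    sp <- mosaic_span(dc, ohc$tree_id, lattice, frame)
    consistency_dev <- abs((b_ohc[["beta3d"]] - b_php[["beta3d"]]) - alpha)
    rows_out[[length(rows_out) + 1]] <- tibble(
      complex_id = dc$tree_id, ohc_id = ohc$tree_id, row = dc$row,
      L_OHC = l_ohc, L_PhP = l_php, L_DC = l_dc,
      alpha = alpha,
      beta_OHC = b_ohc[["beta3d"]], beta_PhP = b_php[["beta3d"]],
      beta_DC = b_dc[["beta3d"]],
      beta_OHC_proj = b_ohc[["beta_proj"]], beta_PhP_proj = b_php[["beta_proj"]],
      beta_DC_proj = b_dc[["beta_proj"]],
      span = sp$span, span_tie = sp$tie_flag,
      partner_ids = paste(sp$partner_ids, collapse = ";"),
      axis_OHC = list(ax_ohc), axis_PhP = list(ax_php), axis_DC = list(ax_dc),
      consistency_dev = consistency_dev,
      consistency_flag = consistency_dev > consistency_tol_deg
    )
  }
  measures <- if (length(rows_out) > 0) bind_rows(rows_out) else tibble()
  excluded <- if (length(excl) > 0) bind_rows(excl) else
    tibble(tree_id = character(), reason = character())
  structure(list(measures = measures, excluded = excluded, lattice = lattice),
            class = "oc_yshapes")
}

#' Measure outer-pillar-cell longitudinal angles
#'
#' OPCs abut row 1, so their beta uses row 1's fitted line.
#'
#' @param ann an [oc_annotation()].
#' @param frame an `oc_frame`.
#' @return tibble `tree_id, L_OPC, beta_OPC, beta_OPC_proj`.
#' @export
measure_opc_angles <- function(ann, frame) {
  opcs <- keep(trees_of_class(ann, "OPC"),
               ~ all(c("OPC_base", "OPC_apex") %in% names(.x$landmarks)))
  if (length(opcs) == 0) {
    return(tibble(tree_id = character(), L_OPC = double(),
                  beta_OPC = double(), beta_OPC_proj = double()))
  }
  bind_rows(map(opcs, function(tr) {
    ax <- principal_axis(tr, "OPC_base", "OPC_apex")
    b <- longitudinal_angle(ax, frame, 1L)
    tibble(tree_id = tr$tree_id,
           L_OPC = path_length(tr, "OPC_base", "OPC_apex"),
           beta_OPC = b[["beta3d"]], beta_OPC_proj = b[["beta_proj"]])
  }))
}

#' Per-row summary of Y-shape measures
#'
#' Mean, SD and n for every numeric field, per row.
#'
#' @param yshapes an `oc_yshapes` from [measure_yshapes()] (or its `measures`
#'   tibble).
#' @return long-format tibble `row, metric, mean, sd, n`.
#' @export
summarize_yshapes <- function(yshapes) {
  m <- if (inherits(yshapes, "oc_yshapes")) yshapes$measures else yshapes
  if (nrow(m) == 0) {
    return(tibble(row = integer(), metric = character(), mean = double(),
                  sd = double(), n = integer()))
  }
  num_cols <- c("L_OHC", "L_PhP", "L_DC", "alpha", "beta_OHC", "beta_PhP",
                "beta_DC", "span")
  m |>
    select(row, dplyr::all_of(num_cols)) |>
    tidyr::pivot_longer(-row, names_to = "metric", values_to = "value") |>
    group_by(row, .data$metric) |>
    summarise(mean = mean(.data$value), sd = sd(.data$value), n = n(),
              .groups = "drop") |>
    arrange(.data$metric, row)
}

#' @export
print.oc_yshapes <- function(x, ...) {
  cat("<oc_yshapes>", nrow(x$measures), "complexes,",
      nrow(x$excluded), "excluded\n")
  if (nrow(x$measures) > 0) print(summarize_yshapes(x), n = 30)
  invisible(x)
}
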
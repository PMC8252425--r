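#' Ordered main path of a fiber
#'
#' The main trunk of an afferent/efferent fiber as an ordered node sequence:
#' the path between the `entry` and `trunk_end` landmarks when present,
#' otherwise the tree diameter (longest geodesic). Collaterals hang off this
#' path.
#'
#' @param fiber a [skeleton_tree()].
#' @return integer vector of node ids in path order.
#' @keywords internal
main_path_ids <- function(fiber) {
  if (all(c("entry", "trunk_end") %in% names(fiber$landmarks))) {
    return(path_node_ids(fiber, "entry", "trunk_end"))
  }
  g <- tree_graph(fiber)
  xyz <- node_xyz(fiber)
  w <- sqrt(rowSums((xyz[match(igraph::as_edgelist(g)[, 1], as.character(fiber$nodes$node_id)), ,
                         drop = FALSE] -
                     xyz[match(igraph::as_edgelist(g)[, 2], as.character(fiber$nodes$node_id)), ,
                         drop = FALSE])^2))
  dia <- igraph::get_diameter(g, weights = w)
  as.integer(igraph::V(g)$name[as.integer(dia)])
}

#' Locate the basal turn of a type-2 fiber
#'
#' Finds the node on the main path maximizing the local direction change: the
#' angle between the mean incoming and outgoing tangent over a window of
#' `window_um` of arc length. The search is restricted to the radial band of
#' the outer-pillar zone when `radial_band` is given (the turn happens right
#' after the fiber bypasses the OPCs; restricting the search keeps bends made
#' while weaving along the DC rows from being mistaken for the turn). If the
#' fiber carries an annotated `turn` landmark it is returned unchanged. A
#' fiber whose maximal direction change is below `min_angle_deg` yields `NA`
#' (excluded from compartment analysis).
#'
#' @param fiber a T2SGN [skeleton_tree()].
#' @param frame an `oc_frame` (orients the radial axis and post-turn
#'   direction).
#' @param window_um tangent-averaging window (default 5 um).
#' @param min_angle_deg minimum turn angle to accept (default 45 degrees).
#' @param radial_band optional `c(lo, hi)` in um along the radial axis
#'   (`bm normal x row direction`), measured from the BM plane point;
#'   see [opc_radial_band()].
#' @return node id of the turn, or `NA_integer_` if no turn is found.
#' @export
locate_turn <- function(fiber, frame, window_um = 5, min_angle_deg = 45,
                        radial_band = NULL) {
  if ("turn" %in% names(fiber$landmarks)) return(fiber$landmarks[["turn"]])
  ids <- main_path_ids(fiber)
  if (length(ids) < 10) {
    warn(sprintf("fiber %s: too few nodes to locate a turn", fiber$tree_id))
    return(NA_integer_)
  }
  xyz <- node_xyz(fiber)[match(ids, fiber$nodes$node_id), , drop = FALSE]
  in_band <- rep(TRUE, length(ids))
  if (!is.null(radial_band)) {
    rad_axis <- unitize(pracma_cross(frame$bm$normal, frame$rows[[1]]$direction))
    rad <- drop(sweep(xyz, 2, frame$bm$point) %*% rad_axis) / NM_PER_UM
    in_band <- rad >= radial_band[1] & rad <= radial_band[2]
    if (!any(in_band)) in_band <- rep(TRUE, length(ids))
  }
  seg <- diff(xyz)
  s <- c(0, cumsum(sqrt(rowSums(seg^2))))
  w_nm <- window_um * NM_PER_UM
  n <- length(ids)
  best_ang <- -Inf
  best_i <- NA_integer_
  for (i in 2:(n - 1)) {
    if (!in_band[i]) next
    j_in <- which(s >= s[i] - w_nm)[1]
    j_out <- tail(which(s <= s[i] + w_nm), 1)
    if (j_in >= i || j_out <= i) next
    v_in <- xyz[i, ] - xyz[j_in, ]
    v_out <- xyz[j_out, ] - xyz[i, ]
    ang <- angle_deg(v_in, v_out)
    if (ang > best_ang) {
      best_ang <- ang
      best_i <- i
    }
  }
  if (!is.finite(best_ang) || best_ang < min_angle_deg) {
    return(NA_integer_)
  }
  ids[best_i]
}

#' Radial band of the outer-pillar zone
#'
#' Radial coordinates (um, along `bm normal x row direction` from the BM plane
#' point) spanned by the OPC base landmarks, widened by `margin_um`. Used to
#' restrict the turn search of [locate_turn()].
#'
#' @param ann an [oc_annotation()].
#' @param frame an `oc_frame`.
#' @param margin_um widening on each side (default 4 um).
#' @return `c(lo, hi)` in um, or `NULL` when no landmarked OPCs exist.
#' @export
opc_radial_band <- function(ann, frame, margin_um = 4) {
  opcs <- keep(trees_of_class(ann, "OPC"),
               ~ "OPC_base" %in% names(.x$landmarks))
  if (length(opcs) == 0) return(NULL)
  pos <- t(vapply(opcs, landmark_xyz, numeric(3), landmark = "OPC_base"))
  rad_axis <- unitize(pracma_cross(frame$bm$normal, frame$rows[[1]]$direction))
  rad <- drop(sweep(pos, 2, frame$bm$point) %*% rad_axis) / NM_PER_UM
  c(min(rad) - margin_um, max(rad) + margin_um)
}

#' Support trunks available for fiber attachment
#'
#' Densified polylines of every DC main trunk (root -> branch point) and OPC
#' (base -> apex), used for nearest-support queries.
#'
#' @param ann an [oc_annotation()].
#' @param step_um resampling step along each trunk (default 1 um).
#' @return list with `xyz` matrix (nm), `support_id`, `support_class`
#'   ("OPC", "DC1", "DC2", "DC3").
#' @keywords internal
support_polylines <- function(ann, step_um = 1) {
  segs <- list()
  add_trunk <- function(tree, from, to, label) {
    if (!all(c(from, to) %in% names(tree$landmarks))) return()
    ids <- path_node_ids(tree, from, to)
    xyz <- node_xyz(tree)[match(ids, tree$nodes$node_id), , drop = FALSE]
    dens <- densify_polyline(xyz, step_um * NM_PER_UM)
    segs[[length(segs) + 1]] <<- list(xyz = dens, id = tree$tree_id, cls = label)
  }
  for (tr in trees_of_class(ann, "DC")) {
    add_trunk(tr, "DC_root", "PhP_branch_point", paste0("DC", tr$row))
  }
  for (tr in trees_of_class(ann, "OPC")) {
    add_trunk(tr, "OPC_base", "OPC_apex", "OPC")
  }
  if (length(segs) == 0) {
    return(list(xyz = matrix(numeric(), ncol = 3), support_id = character(),
                support_class = character()))
  }
  list(
    xyz = do.call(rbind, map(segs, "xyz")),
    support_id = rep(map_chr(segs, "id"), map_int(segs, ~ nrow(.x$xyz))),
    support_class = rep(map_chr(segs, "cls"), map_int(segs, ~ nrow(.x$xyz)))
  )
}

#' @keywords internal
densify_polyline <- function(xyz, step_nm) {
  if (nrow(xyz) < 2) return(xyz)
  out <- list(xyz[1, , drop = FALSE])
  for (i in seq_len(nrow(xyz) - 1)) {
    a <- xyz[i, ]; b <- xyz[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    k <- max(1, ceiling(len / step_nm))
    t <- seq_len(k) / k
    out[[i + 1]] <- cbind(a[1] + t * (b[1] - a[1]),
                          a[2] + t * (b[2] - a[2]),
                          a[3] + t * (b[3] - a[3]))
  }
  do.call(rbind, out)
}

#' Build the height/longitudinal profile of a type-2 fiber
#'
#' Samples every main-path node past the turn: arc length from the turn,
#' longitudinal position (projection on row 1's fitted direction, zero at the
#' turn), height above the BM, and the nearest supporting cell trunk within
#' the attachment radius (else `NA`). Collateral origins are the sampled nodes
#' carrying contacts of this fiber.
#'
#' @param fiber a T2SGN [skeleton_tree()].
#' @param ann the [oc_annotation()] containing supports and contacts.
#' @param frame an `oc_frame`.
#' @param turn_node precomputed turn node id (else [locate_turn()] is called).
#' @param attach_radius_um attachment radius (default 2 um).
#' @param supports precomputed [support_polylines()] (recommended when
#'   profiling many fibers).
#' @return list of class `fiber_profile`: `fiber_id`, `samples` tibble
#'   (`node_id, arc_um, longitudinal_um, height_um, support_id,
#'   support_class, is_collateral_origin`), `turn_node`.
#' @export
build_profile <- function(fiber, ann, frame, turn_node = NULL,
                          attach_radius_um = 2, supports = NULL) {
  if (is.null(turn_node)) turn_node <- locate_turn(fiber, frame)
  if (is.na(turn_node)) {
    abort(sprintf("fiber %s: no turn located", fiber$tree_id),
          class = "cortimorph_no_turn")
  }
  ids <- main_path_ids(fiber)
  ti <- match(turn_node, ids)
  if (is.na(ti)) {
    abort(sprintf("fiber %s: turn node %d not on main path", fiber$tree_id,
                  turn_node), class = "cortimorph_bad_input")
  }
  xyz <- node_xyz(fiber)[match(ids, fiber$nodes$node_id), , drop = FALSE]
  # walk the side of the turn that heads basally
  fwd <- ids[ti:length(ids)]
  bwd <- ids[ti:1]
  pick_dir <- function(seq_ids) {
    p <- xyz[match(seq_ids, ids), , drop = FALSE]
    if (nrow(p) < 2) return(-Inf)
    sum((p[nrow(p), ] - p[1, ]) * frame$basal_hint)
  }
  seq_ids <- if (pick_dir(fwd) >= pick_dir(bwd)) fwd else bwd
  p <- xyz[match(seq_ids, ids), , drop = FALSE]
  arc <- c(0, cumsum(sqrt(rowSums(diff(p)^2)))) / NM_PER_UM
  ln1 <- frame$rows[[1]]
  lon <- drop(sweep(p, 2, p[1, ]) %*% ln1$direction) / NM_PER_UM
  hts <- height_above_bm(p, frame)
  if (is.null(supports)) supports <- support_polylines(ann)
  sup_id <- rep(NA_character_, nrow(p))
  sup_cls <- rep(NA_character_, nrow(p))
  if (nrow(supports$xyz) > 0) {
    nn <- nearest_point_index(p, supports$xyz)
    ok <- nn$dist <= attach_radius_um * NM_PER_UM
    sup_id[ok] <- supports$support_id[nn$index[ok]]
    sup_cls[ok] <- supports$support_class[nn$index[ok]]
  }
  fc <- ann$contacts[ann$contacts$fiber_id == fiber$tree_id, ]
  collat <- seq_ids %in% fc$node_id
  samples <- tibble(node_id = seq_ids, arc_um = arc, longitudinal_um = lon,
                    height_um = hts, support_id = sup_id,
                    support_class = sup_cls, is_collateral_origin = collat)
  structure(list(fiber_id = fiber$tree_id, samples = samples,
                 turn_node = turn_node),
            class = "fiber_profile")
}

#' @keywords internal
nearest_point_index <- function(a, b, chunk = 512L) {
  # nearest row of b for each row of a; chunked squared-distance matrices
  idx <- integer(nrow(a))
  dst <- numeric(nrow(a))
  b2 <- rowSums(b^2)
  starts <- seq(1, nrow(a), by = chunk)
  for (s in starts) {
    e <- min(s + chunk - 1, nrow(a))
    aa <- a[s:e, , drop = FALSE]
    d2 <- outer(rowSums(aa^2), b2, "+") - 2 * tcrossprod(aa, b)
    j <- max.col(-d2, ties.method = "first")
    idx[s:e] <- j
    dst[s:e] <- sqrt(pmax(0, d2[cbind(seq_len(nrow(aa)), j)]))
  }
  list(index = idx, dist = dst)
}

#' Biphasic (climbing / OHC-contact) trajectory fit
#'
#' Splits the post-turn profile at the first collateral origin and fits
#' ordinary least squares of height versus longitudinal position separately on
#' each side (the junction sample belongs to both). The climbing compartment is
#' collateral-free; the contact compartment starts at the first
#' OHC-innervating collateral. Slopes are dimensionless (um height per um
#' longitudinal run); `*_per_dc` versions are scaled by the configured DC
#' pitch.
#'
#' @param profile a `fiber_profile` from [build_profile()].
#' @param dc_pitch_um longitudinal DC spacing used for the per-DC slope
#'   conversion (default 6.8 um).
#' @return object of class `biphasic_fit` with `climbing_slope`,
#'   `contact_slope` (NA when the fiber has no collateral), `breakpoint_index`,
#'   per-DC slopes, residuals and sample counts.
#' @export
fit_biphasic <- function(profile, dc_pitch_um = 6.8) {
  s <- profile$samples
  bp <- which(s$is_collateral_origin)[1]
  fit_side <- function(dat) {
    if (nrow(dat) < 2) return(list(slope = NA_real_, resid = numeric()))
    f <- lm(height_um ~ longitudinal_um, data = dat)
    list(slope = unname(coef(f)[2]), resid = unname(f$residuals))
  }
  if (is.na(bp)) {
    cl <- fit_side(s)
    out <- list(fiber_id = profile$fiber_id, breakpoint_index = NA_integer_,
                climbing_slope = cl$slope, contact_slope = NA_real_,
                climbing_slope_per_dc = cl$slope * dc_pitch_um,
                contact_slope_per_dc = NA_real_,
                residuals_climb = cl$resid, residuals_contact = numeric(),
                n_climb = nrow(s), n_contact = 0L, dc_pitch_um = dc_pitch_um)
    return(structure(out, class = "biphasic_fit"))
  }
  if (bp < 2) {
    abort(sprintf("fiber %s: breakpoint at sample %d leaves an empty climbing compartment",
                  profile$fiber_id, bp), class = "cortimorph_degenerate")
  }
  if (bp > nrow(s) - 1) {
    warn(sprintf("fiber %s: first collateral at the profile end; contact fit undefined",
                 profile$fiber_id))
  }
  cl <- fit_side(s[1:bp, ])
  ct <- fit_side(s[bp:nrow(s), ])
  structure(list(
    fiber_id = profile$fiber_id, breakpoint_index = as.integer(bp),
    climbing_slope = cl$slope, contact_slope = ct$slope,
    climbing_slope_per_dc = cl$slope * dc_pitch_um,
    contact_slope_per_dc = ct$slope * dc_pitch_um,
    residuals_climb = cl$resid, residuals_contact = ct$resid,
    n_climb = bp, n_contact = nrow(s) - bp + 1L, dc_pitch_um = dc_pitch_um),
    class = "biphasic_fit")
}

#' @export
print.biphasic_fit <- function(x, ...) {
  cat(sprintf("<biphasic_fit %s> climbing %.3f, contact %s (breakpoint %s)\n",
              x$fiber_id, x$climbing_slope,
              ifelse(is.na(x$contact_slope), "NA", sprintf("%.3f", x$contact_slope)),
              x$breakpoint_index))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.biphasic_fit <- function(x, ...) {
  tibble(fiber_id = x$fiber_id,
         compartment = c("climbing", "contact"),
         slope = c(x$climbing_slope, x$contact_slope),
         slope_per_dc = c(x$climbing_slope_per_dc, x$contact_slope_per_dc),
         n = c(x$n_climb, x$n_contact))
}

#' @exportS3Method generics::glance
glance.biphasic_fit <- function(x, ...) {
  tibble(fiber_id = x$fiber_id, breakpoint_index = x$breakpoint_index,
         rss_climb = sum(x$residuals_climb^2),
         rss_contact = sum(x$residuals_contact^2),
         n_climb = x$n_climb, n_contact = x$n_contact)
}

#' Label profile samples by trajectory compartment
#' @param profile a `fiber_profile`.
#' @param fit matching `biphasic_fit`.
#' @return the profile samples tibble with a `region` column
#'   (`"climbing"`/`"contact"`).
#' @export
annotate_regions <- function(profile, fit) {
  s <- profile$samples
  bp <- fit$breakpoint_index
  s$region <- if (is.na(bp)) "climbing" else
    ifelse(seq_len(nrow(s)) < bp, "climbing", "contact")
  s$fiber_id <- profile$fiber_id
  s
}

#' Heights of fiber-support contact sites, by support class
#'
#' Climbing-region samples are grouped by the supporting cell class (OPC,
#' DC1-DC3); contact-region samples form their own group (`OHC_contact`). A
#' contact site is one (fiber, support) pair; its height is the mean height of
#' the attached samples.
#'
#' @param region_samples row-bound output of [annotate_regions()] over the
#'   fiber population.
#' @return tibble `group, mean, sd, n` (empty groups reported with n = 0).
#' @export
contact_height_stats <- function(region_samples) {
  sites_climb <- region_samples |>
    filter(.data$region == "climbing", !is.na(.data$support_id)) |>
    group_by(.data$fiber_id, .data$support_id, .data$support_class) |>
    summarise(height = mean(.data$height_um), .groups = "drop")
  sites_contact <- region_samples |>
    filter(.data$region == "contact", !is.na(.data$support_id)) |>
    group_by(.data$fiber_id, .data$support_id) |>
    summarise(height = mean(.data$height_um), .groups = "drop") |>
    mutate(support_class = "OHC_contact")
  groups <- c("OPC", "DC1", "DC2", "DC3", "OHC_contact")
  sites <- bind_rows(sites_climb, sites_contact)
  out <- map(groups, function(gname) {
    h <- sites$height[sites$support_class == gname]
    tibble(group = gname,
           mean = if (length(h) > 0) mean(h) else NA_real_,
           sd = if (length(h) > 1) sd(h) else NA_real_,
           n = length(h))
  })
  bind_rows(out)
}

#' Build a fiber-by-OHC innervation matrix
#'
#' Integer synapse counts from the explicit contact table, never from
#' proximity. Columns cover every labeled OHC (zero-contact OHCs included);
#' rows cover every fiber of the requested class.
#'
#' @param ann an [oc_annotation()] with contacts.
#' @param class `"afferent"` (T2SGN; ribbon + ribbonless) or `"efferent"`
#'   (MOC).
#' @return object of class `innervation_matrix`: `counts` (fibers x OHCs),
#'   `long` (per-class tallies), `target_rows` (named int), `kind`.
#' @export
innervation_matrix <- function(ann, class = c("afferent", "efferent")) {
  class <- match.arg(class)
  fiber_cls <- if (class == "afferent") "T2SGN" else "MOC"
  keep_cls <- if (class == "afferent") {
    c("afferent_ribbon", "afferent_ribbonless")
  } else "efferent"
  fibers <- names(trees_of_class(ann, fiber_cls))
  ohcs <- trees_of_class(ann, "OHC")
  targets <- names(ohcs)
  target_rows <- setNames(map_int(ohcs, "row"), targets)
  cc <- ann$contacts |>
    filter(.data$bouton_class %in% keep_cls, .data$fiber_id %in% fibers)
  counts <- matrix(0L, nrow = length(fibers), ncol = length(targets),
                   dimnames = list(fibers, targets))
  if (nrow(cc) > 0) {
    tb <- table(factor(cc$fiber_id, levels = fibers),
                factor(cc$target_id, levels = targets))
    counts[] <- as.integer(tb)
  }
  long <- cc |>
    dplyr::count(.data$fiber_id, .data$target_id, .data$bouton_class, name = "n")
  structure(list(counts = counts, long = long, target_rows = target_rows,
                 kind = class),
            class = "innervation_matrix")
}

#' @export
print.innervation_matrix <- function(x, ...) {
  cat(sprintf("<innervation_matrix %s> %d fibers x %d OHCs, %d synapses\n",
              x$kind, nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Per-OHC afferent contact counts and ribbon fractions
#'
#' @param imat an afferent [innervation_matrix()].
#' @return list: `per_ohc` tibble (`target_id, row, n_contacts, n_ribbon`),
#'   `per_row` tibble (`row, mean, sd, n_ohc, ribbon_fraction, n_contacts`).
#' @export
afferent_counts <- function(imat) {
  tot <- colSums(imat$counts)
  ribbon <- setNames(rep(0L, ncol(imat$counts)), colnames(imat$counts))
  rb <- imat$long |> filter(.data$bouton_class == "afferent_ribbon") |>
    group_by(.data$target_id) |> summarise(n = sum(.data$n))
  ribbon[rb$target_id] <- rb$n
  per_ohc <- tibble(target_id = colnames(imat$counts),
                    row = unname(imat$target_rows[colnames(imat$counts)]),
                    n_contacts = unname(tot),
                    n_ribbon = unname(ribbon))
  per_row <- per_ohc |>
    group_by(row) |>
    summarise(mean = mean(.data$n_contacts), sd = sd(.data$n_contacts),
              n_ohc = n(),
              ribbon_fraction = ifelse(sum(.data$n_contacts) > 0,
                                       sum(.data$n_ribbon) / sum(.data$n_contacts),
                                       NA_real_),
              n_contacts = sum(.data$n_contacts), .groups = "drop")
  list(per_ohc = per_ohc, per_row = per_row)
}

#' Row specificity of fiber innervation
#'
#' Per fiber: the set of OHC rows contacted, whether the fiber is
#' row-exclusive, and the modal-row fraction of its synapses. Fibers with zero
#' contacts are excluded from the population fractions and counted separately.
#'
#' @param imat an [innervation_matrix()].
#' @return list: `per_fiber` tibble (`fiber_id, n_contacts, rows_contacted,
#'   n_rows, exclusive, modal_row, modal_fraction`), `exclusive_fraction`,
#'   `multi_row_fraction`, `n_fibers_with_contacts`, `n_zero_contact`.
#' @export
row_specificity <- function(imat) {
  rows_of <- imat$target_rows[colnames(imat$counts)]
  per_fiber <- map(rownames(imat$counts), function(f) {
    cnt <- imat$counts[f, ]
    by_row <- tapply(cnt, rows_of, sum)
    by_row <- by_row[by_row > 0]
    n_contacts <- sum(cnt)
    if (n_contacts == 0) {
      return(tibble(fiber_id = f, n_contacts = 0L,
                    rows_contacted = "", n_rows = 0L, exclusive = NA,
                    modal_row = NA_integer_, modal_fraction = NA_real_))
    }
    modal <- which.max(by_row)
    tibble(fiber_id = f, n_contacts = as.integer(n_contacts),
           rows_contacted = paste(names(by_row), collapse = ","),
           n_rows = length(by_row), exclusive = length(by_row) == 1,
           modal_row = as.integer(names(by_row)[modal]),
           modal_fraction = unname(by_row[modal]) / n_contacts)
  }) |> bind_rows()
  withc <- per_fiber |> filter(.data$n_contacts > 0)
  list(per_fiber = per_fiber,
       exclusive_fraction = if (nrow(withc) > 0) mean(withc$exclusive) else NA_real_,
       multi_row_fraction = if (nrow(withc) > 0) mean(!withc$exclusive) else NA_real_,
       n_fibers_with_contacts = nrow(withc),
       n_zero_contact = nrow(per_fiber) - nrow(withc))
}
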
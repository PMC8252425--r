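#' Define the tunnel-of-Corti crossing zone
#'
#' A slab bounded by two parallel planes in which medial olivocochlear (MOC)
#' fibers cross the tunnel radially. Crossings are counted on the slab's
#' mid-plane.
#'
#' @param point 3-vector on the inner bounding plane (nm).
#' @param normal unit 3-vector pointing from the inner to the outer plane
#'   (the radial direction toward the OHC region).
#' @param thickness_um slab thickness in um.
#' @return list of class `tc_zone`.
#' @export
tc_zone <- function(point, normal, thickness_um) {
  structure(list(point = as.numeric(point), normal = unitize(normal),
                 thickness_nm = thickness_um * NM_PER_UM),
            class = "tc_zone")
}

#' Classify one MOC fiber as branched or unbranched
#'
#' Counts distinct tunnel crossings as the number of tree edges transversal to
#' the mid-plane of the tunnel slab (this count is invariant to subdividing
#' edges). Subtype is `branched` for >= 2 crossings, `unbranched` for exactly
#' one. A fiber that never enters the slab cannot be an MOC fiber and raises a
#' classification error.
#'
#' @param fiber an MOC [skeleton_tree()].
#' @param zone a [tc_zone()].
#' @param n_synapses synapse count from the contact table (optional).
#' @return tibble `fiber_id, n_tunnel_crossings, subtype, n_synapses`.
#' @export
classify_moc <- function(fiber, zone, n_synapses = NA_integer_) {
  xyz <- node_xyz(fiber)
  proj <- drop(sweep(xyz, 2, zone$point) %*% zone$normal)
  mid <- zone$thickness_nm / 2
  inside <- proj >= 0 & proj <= zone$thickness_nm
  side <- proj > mid  # TRUE = outer side; nodes exactly on the mid-plane count as inner
  id2i <- match(fiber$edges$from, fiber$nodes$node_id)
  id2j <- match(fiber$edges$to, fiber$nodes$node_id)
  crossings <- sum(side[id2i] != side[id2j])
  if (crossings == 0 && !any(inside)) {
    abort(sprintf("fiber %s never enters the tunnel-crossing zone", fiber$tree_id),
          class = "cortimorph_not_moc")
  }
  tibble(fiber_id = fiber$tree_id,
         n_tunnel_crossings = as.integer(crossings),
         subtype = ifelse(crossings >= 2, "branched", "unbranched"),
         n_synapses = as.integer(n_synapses))
}

#' Classify all MOC fibers of an annotation set
#'
#' @param ann an [oc_annotation()].
#' @param zone a [tc_zone()].
#' @return tibble, one row per MOC fiber, with a `flagged` column for fibers
#'   that never enter the slab (those get subtype `NA`).
#' @export
classify_moc_all <- function(ann, zone) {
  mocs <- trees_of_class(ann, "MOC")
  syn <- ann$contacts |>
    filter(.data$bouton_class == "efferent") |>
    dplyr::count(.data$fiber_id, name = "n_synapses")
  out <- map(mocs, function(tr) {
    ns <- syn$n_synapses[match(tr$tree_id, syn$fiber_id)]
    ns <- if (length(ns) == 0 || is.na(ns)) 0L else ns
    tryCatch(
      classify_moc(tr, zone, ns) |> mutate(flagged = FALSE),
      cortimorph_not_moc = function(e) {
        tibble(fiber_id = tr$tree_id, n_tunnel_crossings = 0L,
               subtype = NA_character_, n_synapses = as.integer(ns),
               flagged = TRUE)
      })
  })
  bind_rows(out)
}

#' Efferent innervation summaries
#'
#' Per-OHC efferent bouton counts, per-row means, and per-subtype synapse
#' statistics and row-distribution shares.
#'
#' @param imat an efferent [innervation_matrix()].
#' @param moc_classes output of [classify_moc_all()].
#' @return list: `per_ohc`, `per_row` (mean +/- SD contacts per OHC),
#'   `per_subtype` (synapse-count mean, SD, range, n) and `row_shares`
#'   (per-subtype percentage of synapses per OHC row).
#' @export
efferent_counts <- function(imat, moc_classes) {
  tot <- colSums(imat$counts)
  per_ohc <- tibble(target_id = colnames(imat$counts),
                    row = unname(imat$target_rows[colnames(imat$counts)]),
                    n_contacts = unname(tot))
  per_row <- per_ohc |>
    group_by(row) |>
    summarise(mean = mean(.data$n_contacts), sd = sd(.data$n_contacts),
              n_ohc = n(), n_contacts = sum(.data$n_contacts), .groups = "drop")
  cls <- moc_classes |> select("fiber_id", "subtype")
  syn <- tibble(fiber_id = rownames(imat$counts),
                n_synapses = rowSums(imat$counts)) |>
    left_join(cls, by = "fiber_id") |>
    filter(!is.na(.data$subtype))
  per_subtype <- syn |>
    group_by(.data$subtype) |>
    summarise(mean = mean(.data$n_synapses), sd = sd(.data$n_synapses),
              min = min(.data$n_synapses), max = max(.data$n_synapses),
              n_fibers = n(), .groups = "drop")
  rows_of <- imat$target_rows[colnames(imat$counts)]
  share <- map(c("branched", "unbranched"), function(st) {
    fb <- syn$fiber_id[syn$subtype == st]
    sub <- imat$counts[rownames(imat$counts) %in% fb, , drop = FALSE]
    by_row <- tapply(colSums(sub), rows_of, sum)
    by_row[is.na(by_row)] <- 0
    tibble(subtype = st, row = as.integer(names(by_row)),
           n_synapses = as.integer(by_row),
           share_pct = as.numeric(100 * by_row / max(1, sum(by_row))))
  }) |> bind_rows()
  list(per_ohc = per_ohc, per_row = per_row, per_subtype = per_subtype,
       row_shares = share)
}
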
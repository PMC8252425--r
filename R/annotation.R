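#' Voxel pitch
#'
#' Physical length of one voxel step along each axis, in nanometres. The
#' reference dataset was imaged at 11 x 11 nm pixels with 40 nm cutting
#' thickness, so its pitch is `voxel_pitch(11, 11, 40)`. Anisotropy is allowed;
#' all axes must be strictly positive.
#'
#' @param dx,dy,dz nm per voxel step along x, y, z.
#' @return named numeric vector of class `voxel_pitch`.
#' @examples
#' voxel_pitch(11, 11, 40)
#' @export
voxel_pitch <- function(dx = 11, dy = 11, dz = 40) {
  p <- c(dx = dx, dy = dy, dz = dz)
  if (!all(is.finite(p)) || any(p <= 0)) {
    abort("voxel pitch must be finite and strictly positive on all axes",
          class = "cortimorph_bad_input")
  }
  structure(p, class = "voxel_pitch")
}

CELL_CLASSES <- c("OHC", "DC", "OPC", "T2SGN", "MOC")
BOUTON_CLASSES <- c("afferent_ribbon", "afferent_ribbonless", "efferent")

#' Construct a skeleton tree
#'
#' One annotated cell or fiber: a node table, an edge table (the graph must be
#' a tree), optional named landmarks, and cell-class/row labels. Positions are
#' physical nanometres.
#'
#' @param tree_id unique identifier string.
#' @param cell_class one of `"OHC"`, `"DC"`, `"OPC"`, `"T2SGN"`, `"MOC"`, or
#'   `NA` for unrecognized trees (retained but flagged).
#' @param row OHC/DC row 1-3; `NA` for fibers and unknown trees.
#' @param nodes tibble with columns `node_id`, `x`, `y`, `z` (nm) and optional
#'   `radius`.
#' @param edges tibble with columns `from`, `to` (node ids).
#' @param landmarks named integer vector of node ids (e.g.
#'   `c(DC_root = 1L, PhP_branch_point = 12L)`).
#' @return a `skeleton_tree` (list).
#' @export
skeleton_tree <- function(tree_id, cell_class = NA_character_, row = NA_integer_,
                          nodes, edges, landmarks = integer()) {
  nodes <- as_tibble(nodes)
  edges <- as_tibble(edges)
  if (!all(c("node_id", "x", "y", "z") %in% names(nodes))) {
    abort("nodes needs columns node_id, x, y, z", class = "cortimorph_bad_input")
  }
  if (nrow(edges) > 0 && !all(c("from", "to") %in% names(edges))) {
    abort("edges needs columns from, to", class = "cortimorph_bad_input")
  }
  if (nrow(edges) == 0) edges <- tibble(from = integer(), to = integer())
  structure(
    list(tree_id = as.character(tree_id),
         cell_class = as.character(cell_class),
         row = as.integer(row),
         nodes = nodes,
         edges = edges[, c("from", "to")],
         landmarks = landmarks),
    class = "skeleton_tree")
}

#' Validate a skeleton tree
#'
#' Checks node-id uniqueness, finite positions, edge endpoints, landmark
#' resolution, the tree property (connected, acyclic) and the row-label
#' invariant for OHC/DC/OPC trees.
#'
#' @param tree a [skeleton_tree()].
#' @return `tree`, invisibly; errors of class `cortimorph_validation` otherwise.
#' @export
validate_tree <- function(tree) {
  nd <- tree$nodes
  if (anyDuplicated(nd$node_id)) {
    abort(sprintf("tree %s: duplicate node ids: %s", tree$tree_id,
                  paste(unique(nd$node_id[duplicated(nd$node_id)]), collapse = ", ")),
          class = "cortimorph_validation")
  }
  if (!all(is.finite(c(nd$x, nd$y, nd$z)))) {
    abort(sprintf("tree %s: non-finite node positions", tree$tree_id),
          class = "cortimorph_validation")
  }
  ed <- tree$edges
  missing_ep <- setdiff(unique(c(ed$from, ed$to)), nd$node_id)
  if (length(missing_ep) > 0) {
    abort(sprintf("tree %s: edges cite absent node ids: %s", tree$tree_id,
                  paste(missing_ep, collapse = ", ")),
          class = "cortimorph_validation")
  }
  if (nrow(nd) > 1) {
    g <- tree_graph(tree)
    if (!igraph::is_connected(g)) {
      abort(sprintf("tree %s: graph is disconnected", tree$tree_id),
            class = "cortimorph_validation")
    }
    if (igraph::ecount(g) != nrow(nd) - 1) {
      abort(sprintf("tree %s: graph has a cycle (%d edges, %d nodes)",
                    tree$tree_id, igraph::ecount(g), nrow(nd)),
            class = "cortimorph_validation")
    }
  }
  lm_bad <- tree$landmarks[!tree$landmarks %in% nd$node_id]
  if (length(lm_bad) > 0) {
    abort(sprintf("tree %s: landmarks refer to absent nodes: %s", tree$tree_id,
                  paste(names(lm_bad), collapse = ", ")),
          class = "cortimorph_validation")
  }
  if (isTRUE(tree$cell_class %in% c("OHC", "DC", "OPC")) && is.na(tree$row)) {
    abort(sprintf("tree %s: %s trees must carry a row label",
                  tree$tree_id, tree$cell_class),
          class = "cortimorph_validation")
  }
  invisible(tree)
}

#' @keywords internal
tree_graph <- function(tree) {
  ids <- as.character(tree$nodes$node_id)
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(tree$edges) > 0) {
    g <- igraph::add_edges(g, rbind(as.character(tree$edges$from),
                                    as.character(tree$edges$to)))
  }
  g
}

#' Node coordinate matrix (nm) in node-table order
#' @keywords internal
node_xyz <- function(tree) {
  as.matrix(tree$nodes[, c("x", "y", "z")])
}

#' Position of a landmark node
#' @param tree a [skeleton_tree()].
#' @param landmark landmark name.
#' @return length-3 numeric (nm).
#' @export
landmark_xyz <- function(tree, landmark) {
  if (!landmark %in% names(tree$landmarks)) {
    abort(sprintf("tree %s: landmark '%s' missing", tree$tree_id, landmark),
          class = "cortimorph_missing_landmark")
  }
  id <- tree$landmarks[[landmark]]
  r <- tree$nodes[match(id, tree$nodes$node_id), ]
  c(x = r$x, y = r$y, z = r$z)
}

#' Construct an annotation set
#'
#' Container for one annotated dataset: voxel pitch, skeleton trees, a
#' fiber-to-OHC contact table, and free-text provenance.
#'
#' @param pitch a [voxel_pitch()].
#' @param trees list of [skeleton_tree()] objects.
#' @param contacts tibble with columns `fiber_id`, `target_id`, `bouton_class`,
#'   `x`, `y`, `z` (nm), `node_id`; empty by default.
#' @param provenance free-text metadata string.
#' @param validate run full validation (default `TRUE`).
#' @return an `oc_annotation` object.
#' @export
oc_annotation <- function(pitch, trees, contacts = empty_contacts(),
                          provenance = "", validate = TRUE) {
  ids <- map_chr(trees, "tree_id")
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate tree ids: %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "cortimorph_validation")
  }
  ann <- structure(
    list(pitch = pitch, trees = setNames(trees, ids),
         contacts = as_tibble(contacts), provenance = provenance),
    class = "oc_annotation")
  if (validate) validate_annotation(ann)
  ann
}

#' @keywords internal
empty_contacts <- function() {
  tibble(fiber_id = character(), target_id = character(),
         bouton_class = character(), x = double(), y = double(), z = double(),
         node_id = integer())
}

#' Validate an annotation set
#'
#' Validates every tree (see [validate_tree()]) and checks that every contact
#' record resolves to existing trees with class-consistent bouton labels
#' (afferent classes only on T2SGN fibers, efferent only on MOC fibers, targets
#' must be OHCs).
#'
#' @param ann an [oc_annotation()].
#' @return `ann`, invisibly.
#' @export
validate_annotation <- function(ann) {
  for (tr in ann$trees) validate_tree(tr)
  validate_contacts(ann$contacts, ann$trees)
  invisible(ann)
}

#' @keywords internal
validate_contacts <- function(contacts, trees) {
  if (nrow(contacts) == 0) return(invisible(contacts))
  classes <- map_chr(trees, "cell_class")
  for (i in seq_len(nrow(contacts))) {
    row_i <- contacts[i, ]
    if (!row_i$fiber_id %in% names(trees)) {
      abort(sprintf("contact row %d: unknown fiber '%s'", i, row_i$fiber_id),
            class = "cortimorph_validation")
    }
    if (!row_i$target_id %in% names(trees)) {
      abort(sprintf("contact row %d: unknown target '%s'", i, row_i$target_id),
            class = "cortimorph_validation")
    }
    fc <- classes[[row_i$fiber_id]]
    if (!row_i$bouton_class %in% BOUTON_CLASSES) {
      abort(sprintf("contact row %d: unknown bouton class '%s'", i,
                    row_i$bouton_class), class = "cortimorph_validation")
    }
    ok <- (row_i$bouton_class == "efferent" && identical(fc, "MOC")) ||
      (row_i$bouton_class != "efferent" && identical(fc, "T2SGN"))
    if (!ok) {
      abort(sprintf(
        "contact row %d: bouton class '%s' inconsistent with fiber class '%s'",
        i, row_i$bouton_class, fc), class = "cortimorph_validation")
    }
    if (!identical(classes[[row_i$target_id]], "OHC")) {
      abort(sprintf("contact row %d: target '%s' is not an OHC", i,
                    row_i$target_id), class = "cortimorph_validation")
    }
  }
  invisible(contacts)
}

#' Tabular overview of the trees in an annotation set
#'
#' @param ann an [oc_annotation()].
#' @return tibble with one row per tree: id, class, row, node/edge/landmark
#'   counts.
#' @export
tree_table <- function(ann) {
  tibble(
    tree_id = map_chr(ann$trees, "tree_id"),
    cell_class = map_chr(ann$trees, "cell_class"),
    row = map_int(ann$trees, "row"),
    n_nodes = map_int(ann$trees, ~ nrow(.x$nodes)),
    n_edges = map_int(ann$trees, ~ nrow(.x$edges)),
    landmarks = map_chr(ann$trees, ~ paste(names(.x$landmarks), collapse = ","))
  )
}

#' Subset trees by cell class
#' @param ann an [oc_annotation()].
#' @param class cell class string.
#' @return named list of trees.
#' @export
trees_of_class <- function(ann, class) {
  keep(ann$trees, ~ identical(.x$cell_class, class))
}

#' @export
print.oc_annotation <- function(x, ...) {
  tt <- tree_table(x)
  cat("<oc_annotation>\n")
  cat(sprintf("  pitch: %g x %g x %g nm\n", x$pitch[1], x$pitch[2], x$pitch[3]))
  cls <- table(tt$cell_class, useNA = "ifany")
  cat("  trees:", nrow(tt), "(", paste(names(cls), cls, sep = "=", collapse = ", "), ")\n")
  cat("  contacts:", nrow(x$contacts), "\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}
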
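#' Parse a tree name into cell class and row
#'
#' Default naming grammar: `<CLASS><row>_<id>`, e.g. `OHC2_017` (class OHC,
#' row 2) or `MOC_007` (no row). Unknown names yield class `NA` and the tree is
#' retained but flagged by the readers.
#'
#' @param name tree name string(s).
#' @param grammar regex with named-capture-free groups: group 1 = class,
#'   group 2 = optional row digit.
#' @return tibble with columns `cell_class`, `row`.
#' @export
parse_tree_name <- function(name,
                            grammar = "^(OHC|DC|OPC|T2SGN|MOC)([1-3])?_([0-9A-Za-z]+)$") {
  m <- regmatches(name, regexec(grammar, name))
  tibble(
    cell_class = map_chr(m, ~ if (length(.x) == 0) NA_character_ else .x[2]),
    row = map_int(m, ~ {
      if (length(.x) == 0 || .x[3] == "") NA_integer_ else as.integer(.x[3])
    })
  )
}

LANDMARK_PREFIX <- "landmark:"

#' Read a webKNOSSOS-style NML skeleton file
#'
#' Parses `<thing>` trees with `<node>`/`<edge>` children. Integer voxel
#' coordinates are converted to physical nanometres by componentwise
#' multiplication with `pitch` (0-based voxel indices, node centres). Cell
#' class and row are parsed from the tree `name` attribute via
#' [parse_tree_name()]; trees that do not match the grammar are retained with
#' class `NA` and a warning. Landmarks are read from `<comment>` elements whose
#' content starts with `landmark:`.
#'
#' @param path NML file path.
#' @param pitch a [voxel_pitch()].
#' @param grammar naming grammar passed to [parse_tree_name()].
#' @return an [oc_annotation()] (without contacts).
#' @export
read_nml <- function(path, pitch = voxel_pitch(), grammar = NULL) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(sprintf("malformed NML XML in '%s': %s", path, conditionMessage(e)),
          class = "cortimorph_parse")
  })
  things <- xml2::xml_find_all(doc, ".//thing")
  trees <- map(things, function(th) {
    name <- xml2::xml_attr(th, "name")
    nd <- xml2::xml_find_all(th, ".//node")
    nodes <- tibble(
      node_id = as.integer(xml2::xml_attr(nd, "id")),
      x = as.numeric(xml2::xml_attr(nd, "x")) * pitch[["dx"]],
      y = as.numeric(xml2::xml_attr(nd, "y")) * pitch[["dy"]],
      z = as.numeric(xml2::xml_attr(nd, "z")) * pitch[["dz"]],
      radius = as.numeric(xml2::xml_attr(nd, "radius"))
    )
    eg <- xml2::xml_find_all(th, ".//edge")
    edges <- tibble(
      from = as.integer(xml2::xml_attr(eg, "source")),
      to = as.integer(xml2::xml_attr(eg, "target"))
    )
    cm <- xml2::xml_find_all(th, ".//comment")
    lm <- integer()
    if (length(cm) > 0) {
      content <- xml2::xml_attr(cm, "content")
      is_lm <- startsWith(content, LANDMARK_PREFIX)
      lm <- setNames(as.integer(xml2::xml_attr(cm, "node")[is_lm]),
                     sub(LANDMARK_PREFIX, "", content[is_lm], fixed = TRUE))
    }
    lab <- if (is.null(grammar)) parse_tree_name(name) else parse_tree_name(name, grammar)
    skeleton_tree(name, lab$cell_class[1], lab$row[1], nodes, edges, lm)
  })
  unknown <- map_chr(trees, "tree_id")[is.na(map_chr(trees, "cell_class"))]
  if (length(unknown) > 0) {
    warn(sprintf("%d tree(s) did not match the naming grammar and were kept unclassed: %s",
                 length(unknown), paste(unknown, collapse = ", ")))
  }
  oc_annotation(pitch, trees, provenance = sprintf("read_nml(%s)", basename(path)))
}

#' Write an annotation set as NML
#' @keywords internal
write_nml <- function(ann, path) {
  doc <- xml2::xml_new_root("things")
  par <- xml2::xml_add_child(doc, "parameters")
  sc <- xml2::xml_add_child(par, "scale")
  xml2::xml_set_attrs(sc, c(x = ann$pitch[["dx"]], y = ann$pitch[["dy"]],
                            z = ann$pitch[["dz"]]))
  tid <- 0L
  for (tr in ann$trees) {
    tid <- tid + 1L
    th <- xml2::xml_add_child(doc, "thing")
    xml2::xml_set_attrs(th, c(id = tid, name = tr$tree_id))
    nds <- xml2::xml_add_child(th, "nodes")
    vox <- cbind(round(tr$nodes$x / ann$pitch[["dx"]]),
                 round(tr$nodes$y / ann$pitch[["dy"]]),
                 round(tr$nodes$z / ann$pitch[["dz"]]))
    for (i in seq_len(nrow(tr$nodes))) {
      nd <- xml2::xml_add_child(nds, "node")
      at <- c(id = tr$nodes$node_id[i], x = vox[i, 1], y = vox[i, 2], z = vox[i, 3])
      if (!is.null(tr$nodes$radius) && !is.na(tr$nodes$radius[i])) {
        at <- c(at, radius = tr$nodes$radius[i])
      }
      xml2::xml_set_attrs(nd, at)
    }
    egs <- xml2::xml_add_child(th, "edges")
    for (i in seq_len(nrow(tr$edges))) {
      eg <- xml2::xml_add_child(egs, "edge")
      xml2::xml_set_attrs(eg, c(source = tr$edges$from[i], target = tr$edges$to[i]))
    }
    if (length(tr$landmarks) > 0) {
      cms <- xml2::xml_add_child(th, "comments")
      for (nm in names(tr$landmarks)) {
        cm <- xml2::xml_add_child(cms, "comment")
        xml2::xml_set_attrs(cm, c(node = tr$landmarks[[nm]],
                                  content = paste0(LANDMARK_PREFIX, nm)))
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read SWC skeleton files
#'
#' Standard 7-column SWC (`id type x y z radius parent`), one file per cell;
#' parent links become undirected edges, the parent `-1` node is recorded as a
#' `root` landmark. Coordinates are voxel indices scaled by `pitch`.
#'
#' @param paths character vector of SWC files.
#' @param pitch a [voxel_pitch()].
#' @param labels optional tibble with columns `path`, `cell_class`, `row`
#'   (matched on `basename(path)`); otherwise labels are parsed from filenames
#'   via [parse_tree_name()].
#' @return an [oc_annotation()].
#' @export
read_swc <- function(paths, pitch = voxel_pitch(), labels = NULL) {
  trees <- map(paths, function(p) {
    dat <- utils::read.table(p, comment.char = "#",
                             col.names = c("id", "type", "x", "y", "z", "radius", "parent"))
    stem <- sub("\\.swc$", "", basename(p))
    if (anyDuplicated(dat$id)) {
      abort(sprintf("%s: duplicate SWC node ids", p), class = "cortimorph_validation")
    }
    # cycle check on parent chains
    par <- setNames(dat$parent, dat$id)
    for (start in dat$id) {
      seen <- integer()
      cur <- start
      while (cur != -1) {
        if (cur %in% seen) {
          abort(sprintf("%s: cyclic parent chain at node %d", p, start),
                class = "cortimorph_validation")
        }
        seen <- c(seen, cur)
        cur <- par[[as.character(cur)]]
        if (is.null(cur)) break
      }
    }
    nodes <- tibble(node_id = as.integer(dat$id),
                    x = dat$x * pitch[["dx"]], y = dat$y * pitch[["dy"]],
                    z = dat$z * pitch[["dz"]], radius = dat$radius)
    has_par <- dat$parent != -1
    edges <- tibble(from = as.integer(dat$parent[has_par]),
                    to = as.integer(dat$id[has_par]))
    roots <- dat$id[dat$parent == -1]
    lm <- if (length(roots) > 0) c(root = as.integer(roots[1])) else integer()
    if (is.null(labels)) {
      lab <- parse_tree_name(stem)
      cls <- lab$cell_class[1]; rw <- lab$row[1]
    } else {
      hit <- labels[match(basename(p), basename(labels$path)), ]
      cls <- hit$cell_class[1]; rw <- as.integer(hit$row[1])
    }
    skeleton_tree(stem, cls, rw, nodes, edges, lm)
  })
  oc_annotation(pitch, trees,
                provenance = sprintf("read_swc(%d files)", length(paths)))
}

#' @keywords internal
write_swc_one <- function(tree, path, pitch) {
  # orient edges from a root (landmark root, else first node)
  g <- tree_graph(tree)
  root <- if ("root" %in% names(tree$landmarks)) {
    as.character(tree$landmarks[["root"]])
  } else as.character(tree$nodes$node_id[1])
  parent <- rep(-1L, nrow(tree$nodes))
  names(parent) <- as.character(tree$nodes$node_id)
  if (nrow(tree$nodes) > 1 && igraph::ecount(g) > 0) {
    bfs <- igraph::bfs(g, root = root, father = TRUE, unreachable = FALSE)
    fa <- as.integer(bfs$father)
    vn <- igraph::V(g)$name
    for (i in seq_along(vn)) {
      if (!is.na(fa[i])) parent[vn[i]] <- as.integer(vn[fa[i]])
    }
  }
  dat <- data.frame(
    id = tree$nodes$node_id, type = 0L,
    x = round(tree$nodes$x / pitch[["dx"]]),
    y = round(tree$nodes$y / pitch[["dy"]]),
    z = round(tree$nodes$z / pitch[["dz"]]),
    radius = ifelse(is.na(tree$nodes$radius %||% NA), 1, tree$nodes$radius),
    parent = parent[as.character(tree$nodes$node_id)]
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s class=%s row=%s", tree$tree_id, tree$cell_class,
                     tree$row), con)
  utils::write.table(dat, con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a fiber-to-OHC contact table
#'
#' CSV with header `fiber_id, target_id, bouton_class, x, y, z, node_id`;
#' coordinates are voxel indices scaled by the annotation's pitch. Records are
#' validated against the annotation's trees (existence and class consistency)
#' and appended.
#'
#' @param path CSV path.
#' @param ann an [oc_annotation()].
#' @return `ann` with the contacts appended.
#' @export
read_contacts <- function(path, ann) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fiber_id", "target_id", "bouton_class", "x", "y", "z", "node_id")
  if (!all(need %in% names(dat))) {
    abort(sprintf("contact table must have columns %s", paste(need, collapse = ", ")),
          class = "cortimorph_parse")
  }
  if (nrow(dat) == 0) {
    warn(sprintf("contact table '%s' is empty", basename(path)))
    return(ann)
  }
  contacts <- tibble(
    fiber_id = as.character(dat$fiber_id),
    target_id = as.character(dat$target_id),
    bouton_class = as.character(dat$bouton_class),
    x = dat$x * ann$pitch[["dx"]],
    y = dat$y * ann$pitch[["dy"]],
    z = dat$z * ann$pitch[["dz"]],
    node_id = as.integer(dat$node_id)
  )
  validate_contacts(contacts, ann$trees)
  ann$contacts <- bind_rows(ann$contacts, contacts)
  ann
}

#' @keywords internal
write_contacts_csv <- function(ann, path) {
  dat <- ann$contacts
  out <- data.frame(
    fiber_id = dat$fiber_id, target_id = dat$target_id,
    bouton_class = dat$bouton_class,
    x = round(dat$x / ann$pitch[["dx"]]),
    y = round(dat$y / ann$pitch[["dy"]]),
    z = round(dat$z / ann$pitch[["dz"]]),
    node_id = dat$node_id
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an annotation set
#'
#' Round-trip contract: `read(write(x))` reproduces topology and labels exactly
#' and node positions to within half a voxel per axis (voxel quantization).
#'
#' @param ann an [oc_annotation()].
#' @param path output file (`nml`, `contacts-csv`) or directory (`swc`).
#' @param format one of `"nml"`, `"swc"`, `"contacts-csv"`.
#' @return the path, invisibly.
#' @export
write_annotation <- function(ann, path, format = c("nml", "swc", "contacts-csv")) {
  format <- tryCatch(match.arg(format), error = function(e) {
    abort(sprintf("unsupported format '%s'", format[1]), class = "cortimorph_bad_input")
  })
  switch(format,
    nml = write_nml(ann, path),
    `contacts-csv` = write_contacts_csv(ann, path),
    swc = {
      dir.create(path, showWarnings = FALSE, recursive = TRUE)
      for (tr in ann$trees) {
        write_swc_one(tr, file.path(path, paste0(tr$tree_id, ".swc")), ann$pitch)
      }
      invisible(path)
    })
}
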
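#' Fit the basilar-membrane plane from Deiters-cell roots
#'
#' Total-least-squares plane through the root points: the normal is the
#' smallest principal component of the centred point cloud (via SVD). The
#' normal is oriented so that `orient_toward` (typically the mean OHC apical
#' landmark, i.e. the reticular-lamina side) lies on the positive side.
#'
#' @param points numeric matrix or data frame with 3 columns (nm), one DC root
#'   per row; at least 3 non-collinear points.
#' @param orient_toward optional 3-vector; flips the normal so this point has
#'   positive signed distance.
#' @return list of class `oc_plane` with `point` (centroid, nm) and unit
#'   `normal`.
#' @export
fit_bm_plane <- function(points, orient_toward = NULL) {
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  if (nrow(pts) < 3) {
    abort("plane fit needs at least 3 points", class = "cortimorph_degenerate")
  }
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) {
    abort("points are collinear; plane is undetermined",
          class = "cortimorph_degenerate")
  }
  normal <- sv$v[, 3]
  if (!is.null(orient_toward) && sum((orient_toward - ctr) * normal) < 0) {
    normal <- -normal
  }
  structure(list(point = ctr, normal = unitize(normal, tol = 1e-9)),
            class = "oc_plane")
}

#' Fit a Deiters-cell row line
#'
#' First principal axis of the centred points of one DC row; the sign is chosen
#' so the direction points toward the cochlear base (`direction %*% basal_hint
#' > 0`).
#'
#' @param points matrix/data frame of that row's DC roots (nm), >= 2 distinct.
#' @param basal_hint 3-vector indicating the basal direction.
#' @param row row label carried along (1-3).
#' @return list of class `oc_row_line` with `row`, `point`, unit `direction`.
#' @export
fit_row_line <- function(points, basal_hint, row = NA_integer_) {
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2, ctr)
  if (nrow(pts) < 2 || max(abs(cen)) < 1e-12) {
    abort("row-line fit needs >= 2 distinct points", class = "cortimorph_degenerate")
  }
  sv <- svd(cen)
  dir <- sv$v[, 1]
  if (sum(dir * basal_hint) < 0) dir <- -dir
  structure(list(row = as.integer(row), point = ctr, direction = unitize(dir, 1e-9)),
            class = "oc_row_line")
}

#' Build the measurement reference frame
#'
#' BM plane from all DC root landmarks (all rows pooled), one fitted line per
#' DC row, and the basal orientation convention. The plane normal is oriented
#' toward the mean OHC cuticular-plate landmark (reticular-lamina side).
#'
#' @param ann an [oc_annotation()] with landmarked DC (and OHC) trees.
#' @param basal_hint 3-vector disambiguating the cochlear-base direction
#'   (required; the annotation itself does not encode it).
#' @param row_plane_tol_deg maximum allowed angle between each row line and
#'   the BM plane (QC check; default 15 degrees).
#' @return list of class `oc_frame`: `bm`, `rows` (list indexed 1-3),
#'   `basal_hint`.
#' @export
build_reference_frame <- function(ann, basal_hint, row_plane_tol_deg = 15) {
  dcs <- trees_of_class(ann, "DC")
  roots <- keep(dcs, ~ "DC_root" %in% names(.x$landmarks))
  if (length(roots) < 3) {
    abort("need at least 3 DC trees with a DC_root landmark",
          class = "cortimorph_degenerate")
  }
  pts <- t(vapply(roots, landmark_xyz, numeric(3), landmark = "DC_root"))
  ohcs <- trees_of_class(ann, "OHC")
  apical <- keep(ohcs, ~ "cuticular_plate" %in% names(.x$landmarks))
  orient <- if (length(apical) > 0) {
    colMeans(t(vapply(apical, landmark_xyz, numeric(3), landmark = "cuticular_plate")))
  } else NULL
  bm <- fit_bm_plane(pts, orient_toward = orient)
  rows_present <- sort(unique(map_int(roots, "row")))
  lines <- map(rows_present, function(r) {
    rp <- pts[map_int(roots, "row") == r, , drop = FALSE]
    ln <- fit_row_line(rp, basal_hint, row = r)
    tilt <- abs(90 - angle_deg(ln$direction, bm$normal))
    if (tilt > row_plane_tol_deg) {
      warn(sprintf("row %d line is %.1f deg out of the BM plane (tolerance %g)",
                   r, tilt, row_plane_tol_deg))
    }
    ln
  })
  lines <- setNames(lines, rows_present)
  if (length(lines) >= 2) {
    dirs <- map(lines, "direction")
    for (i in seq_along(dirs)[-1]) {
      if (angle_deg(dirs[[1]], dirs[[i]]) > 30) {
        warn("row directions differ by more than 30 degrees")
      }
    }
  }
  structure(list(bm = bm, rows = lines, basal_hint = unitize(basal_hint)),
            class = "oc_frame")
}

#' Signed height above the basilar membrane
#'
#' Perpendicular distance from `point` to the BM plane along its oriented
#' normal, in micrometres. Points on the non-reticular side come out negative.
#'
#' @param point 3-vector or matrix of row vectors (nm).
#' @param bm an `oc_plane` (or an `oc_frame`, whose `$bm` is used).
#' @return numeric, um.
#' @export
height_above_bm <- function(point, bm) {
  if (inherits(bm, "oc_frame")) bm <- bm$bm
  pts <- if (is.matrix(point)) point else matrix(point, ncol = 3)
  if (!all(is.finite(pts))) abort("non-finite point", class = "cortimorph_bad_input")
  drop(sweep(pts, 2, bm$point) %*% bm$normal) / NM_PER_UM
}

#' Serialize a reference frame to JSON
#' @param frame an `oc_frame`.
#' @param path optional output path; if `NULL`, the JSON string is returned.
#' @return path or JSON string.
#' @export
frame_to_json <- function(frame, path = NULL) {
  obj <- list(
    bm = list(point = frame$bm$point, normal = frame$bm$normal),
    rows = map(frame$rows, ~ list(row = .x$row, point = .x$point,
                                  direction = .x$direction)),
    basal_hint = frame$basal_hint
  )
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = FALSE)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Deserialize a reference frame from JSON
#' @param path JSON file path or JSON string.
#' @return an `oc_frame`.
#' @export
frame_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  rows <- map(obj$rows, ~ structure(
    list(row = as.integer(.x$row), point = as.numeric(.x$point),
         direction = as.numeric(.x$direction)), class = "oc_row_line"))
  structure(list(
    bm = structure(list(point = as.numeric(obj$bm$point),
                        normal = as.numeric(obj$bm$normal)), class = "oc_plane"),
    rows = rows, basal_hint = as.numeric(obj$basal_hint)), class = "oc_frame")
}
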
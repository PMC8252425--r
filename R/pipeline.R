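#' Number of distinct fibers attached per supporting cell
#'
#' Counts, for every DC (and OPC) trunk, the distinct type-2 fibers with at
#' least one profile sample attached to it.
#'
#' @param region_samples row-bound [annotate_regions()] samples of the fiber
#'   population (a plain bound `samples` tibble with `fiber_id` works too).
#' @return tibble `support_id, support_class, n_fibers`.
#' @export
dc_fiber_abundance <- function(region_samples) {
  region_samples |>
    filter(!is.na(.data$support_id)) |>
    distinct(.data$fiber_id, .data$support_id, .data$support_class) |>
    group_by(.data$support_id, .data$support_class) |>
    summarise(n_fibers = n(), .groups = "drop")
}

#' Profile and fit the whole type-2 fiber population
#'
#' Locates each fiber's turn, builds its profile, fits the biphasic
#' compartment model and annotates regions. Fibers without a detectable turn
#' are skipped and listed.
#'
#' @param ann an [oc_annotation()].
#' @param frame an `oc_frame`.
#' @param dc_pitch_um per-DC slope conversion pitch (default 6.8).
#' @param attach_radius_um attachment radius (default 2).
#' @return list: `profiles`, `fits`, `region_samples` (bound tibble),
#'   `skipped` (fiber ids without a turn).
#' @export
analyze_fibers <- function(ann, frame, dc_pitch_um = 6.8, attach_radius_um = 2) {
  fibers <- trees_of_class(ann, "T2SGN")
  supports <- support_polylines(ann)
  band <- opc_radial_band(ann, frame)
  profiles <- list()
  fits <- list()
  skipped <- character()
  for (tr in fibers) {
    tn <- locate_turn(tr, frame, radial_band = band)
    if (is.na(tn)) {
      skipped <- c(skipped, tr$tree_id)
      next
    }
    pr <- build_profile(tr, ann, frame, turn_node = tn,
                        attach_radius_um = attach_radius_um,
                        supports = supports)
    ft <- fit_biphasic(pr, dc_pitch_um = dc_pitch_um)
    profiles[[tr$tree_id]] <- pr
    fits[[tr$tree_id]] <- ft
  }
  region_samples <- if (length(profiles) > 0) {
    bind_rows(map2(profiles, fits, annotate_regions))
  } else tibble()
  list(profiles = profiles, fits = fits, region_samples = region_samples,
       skipped = skipped)
}

#' Run the full analysis pipeline
#'
#' Reference frame -> Y-shape morphometry -> type-2 fiber analysis -> MOC
#' classification -> summary statistics. Stages degrade gracefully: without
#' contacts the innervation stages are skipped with a warning while the
#' geometry report is still produced.
#'
#' @param ann an [oc_annotation()], or an `oc_synthesis` (its annotation,
#'   basal hint and tunnel zone are used).
#' @param basal_hint 3-vector toward the cochlear base (required for plain
#'   annotations).
#' @param zone a [tc_zone()] for MOC classification (optional; MOC stage is
#'   skipped without it).
#' @param dc_pitch_um per-DC slope conversion pitch.
#' @return list of class `oc_report` with elements `frame`, `yshapes`,
#'   `yshape_summary`, `opc`, `fibers`, `height_stats`, `afferent`,
#'   `specificity`, `abundance`, `moc`, `efferent`, `qc`.
#' @export
oc_run_pipeline <- function(ann, basal_hint = NULL, zone = NULL,
                            dc_pitch_um = 6.8) {
  if (inherits(ann, "oc_synthesis")) {
    if (is.null(basal_hint)) basal_hint <- ann$ledger$basal_hint
    if (is.null(zone)) zone <- ann$tc_zone
    ann <- ann$annotation
  }
  if (is.null(basal_hint)) {
    abort("basal_hint is required (the annotation does not encode the basal direction)",
          class = "cortimorph_bad_input")
  }
  frame <- build_reference_frame(ann, basal_hint)
  ys <- measure_yshapes(ann, frame)
  opc <- measure_opc_angles(ann, frame)
  out <- list(frame = frame, yshapes = ys, yshape_summary = summarize_yshapes(ys),
              opc = opc)
  qc <- list(excluded_complexes = nrow(ys$excluded),
             consistency_flags = sum(ys$measures$consistency_flag %||% 0),
             span_ties = sum(ys$measures$span_tie %||% 0))
  has_contacts <- nrow(ann$contacts) > 0
  has_t2 <- length(trees_of_class(ann, "T2SGN")) > 0
  if (has_t2) {
    fa <- analyze_fibers(ann, frame, dc_pitch_um = dc_pitch_um)
    out$fibers <- fa
    qc$fibers_without_turn <- length(fa$skipped)
    if (nrow(fa$region_samples) > 0) {
      out$height_stats <- contact_height_stats(fa$region_samples)
      out$abundance <- dc_fiber_abundance(fa$region_samples)
      qc$negative_heights <- sum(fa$region_samples$height_um < 0)
    }
    if (has_contacts) {
      imat <- innervation_matrix(ann, "afferent")
      out$afferent <- afferent_counts(imat)
      out$afferent$matrix <- imat
      out$specificity <- row_specificity(imat)
    } else {
      warn("no contact records: afferent innervation stages skipped")
    }
  }
  if (length(trees_of_class(ann, "MOC")) > 0) {
    if (!is.null(zone)) {
      out$moc <- classify_moc_all(ann, zone)
      qc$moc_flagged <- sum(out$moc$flagged)
      if (has_contacts) {
        emat <- innervation_matrix(ann, "efferent")
        out$efferent <- efferent_counts(emat, out$moc)
        out$efferent$matrix <- emat
        out$efferent$specificity <- row_specificity(emat)
      }
    } else {
      warn("no tunnel-crossing zone supplied: MOC stage skipped")
    }
  }
  out$qc <- qc
  structure(out, class = "oc_report")
}

#' @export
print.oc_report <- function(x, ...) {
  cat("<oc_report>\n")
  cat(sprintf("  complexes measured: %d (excluded %d)\n",
              nrow(x$yshapes$measures), nrow(x$yshapes$excluded)))
  if (!is.null(x$fibers)) {
    cat(sprintf("  type-2 fibers profiled: %d (no turn: %d)\n",
                length(x$fibers$profiles), length(x$fibers$skipped)))
  }
  if (!is.null(x$moc)) {
    cat(sprintf("  MOC fibers classified: %d (branched %d)\n",
                nrow(x$moc), sum(x$moc$subtype == "branched", na.rm = TRUE)))
  }
  invisible(x)
}

#' Write a figure-keyed summary JSON of a pipeline report
#'
#' Headline numbers of every stage under stable keys (`fig1c` ... `fig3d`),
#' with a schema version. Every number is computed by the pipeline, none is
#' stored.
#'
#' @param report an `oc_report`.
#' @param path output path; `NULL` returns the list invisibly.
#' @return the summary list, invisibly.
#' @export
report_to_json <- function(report, path = NULL) {
  ysm <- report$yshape_summary
  pull_metric <- function(metric) {
    m <- ysm[ysm$metric == metric, ]
    map(1:3, ~ {
      r <- m[m$row == .x, ]
      if (nrow(r) == 0) NULL else list(mean = r$mean, sd = r$sd, n = r$n)
    })
  }
  js <- list(schema_version = "1.0")
  if (nrow(ysm) > 0) {
    js$fig1c <- pull_metric("L_OHC")
    js$fig1d <- pull_metric("L_PhP")
    js$fig1e <- pull_metric("L_DC")
    js$fig1f <- pull_metric("alpha")
    js$fig1g <- pull_metric("beta_DC")
    js$fig1h <- list(beta_OHC = pull_metric("beta_OHC"),
                     beta_PhP = pull_metric("beta_PhP"),
                     beta_OPC = if (nrow(report$opc) > 0) {
                       list(mean = mean(report$opc$beta_OPC),
                            sd = sd(report$opc$beta_OPC),
                            n = nrow(report$opc))
                     } else NULL)
    js$fig1i <- pull_metric("span")
  }
  if (!is.null(report$fibers) && length(report$fibers$fits) > 0) {
    sl <- bind_rows(map(report$fibers$fits, tidy))
    cl <- sl$slope[sl$compartment == "climbing"]
    ct <- sl$slope[sl$compartment == "contact"]
    js$fig2e <- list(climbing = list(mean = mean(cl, na.rm = TRUE),
                                     sd = sd(cl), n = sum(!is.na(cl))),
                     contact = list(mean = mean(ct, na.rm = TRUE),
                                    sd = sd(ct, na.rm = TRUE),
                                    n = sum(!is.na(ct))))
  }
  if (!is.null(report$height_stats)) js$fig2f <- report$height_stats
  if (!is.null(report$abundance)) {
    ab <- report$abundance |>
      filter(startsWith(.data$support_class, "DC")) |>
      group_by(.data$support_class) |>
      summarise(mean = mean(.data$n_fibers), sd = sd(.data$n_fibers),
                n = n(), .groups = "drop")
    js$fig2g <- ab
  }
  if (!is.null(report$afferent)) {
    js$fig2h <- report$afferent$per_row
    js$fig2i <- list(exclusive_fraction = report$specificity$exclusive_fraction,
                     n = report$specificity$n_fibers_with_contacts)
  }
  if (!is.null(report$efferent)) {
    js$fig3c <- report$efferent$per_row
    js$fig3d <- list(per_subtype = report$efferent$per_subtype,
                     row_shares = report$efferent$row_shares)
  }
  if (!is.null(path)) {
    jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(js)
}
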
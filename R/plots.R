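#' Per-row Y-shape geometry plot
#'
#' Jittered per-complex values with mean +/- SD, facetted by metric.
#'
#' @param yshapes an `oc_yshapes` (or its `measures` tibble).
#' @param metrics which measures to show.
#' @return a ggplot object.
#' @export
plot_yshape_summary <- function(yshapes,
                                metrics = c("L_OHC", "L_PhP", "L_DC",
                                            "alpha", "beta_DC")) {
  m <- if (inherits(yshapes, "oc_yshapes")) yshapes$measures else yshapes
  long <- m |>
    select(row, dplyr::all_of(metrics)) |>
    tidyr::pivot_longer(-row, names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$row), y = .data$value)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_sdl,
                          fun.args = list(mult = 1),
                          geom = "pointrange", colour = "firebrick") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "OHC row", y = NULL,
                  title = "Y-shape geometry by row (mean ± SD)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.oc_yshapes <- function(object, ...) plot_yshape_summary(object, ...)

#' Height-versus-longitudinal-position plot of fiber profiles
#'
#' The biphasic trajectory of each type-2 fiber; the climbing and OHC-contact
#' compartments are coloured when fits are supplied.
#'
#' @param region_samples bound [annotate_regions()] samples (or a profile's
#'   `samples` with a `fiber_id` column).
#' @return a ggplot object.
#' @export
plot_fiber_profiles <- function(region_samples) {
  has_region <- "region" %in% names(region_samples)
  p <- ggplot2::ggplot(region_samples,
                       ggplot2::aes(x = .data$longitudinal_um,
                                    y = .data$height_um,
                                    group = .data$fiber_id))
  p <- if (has_region) {
    p + ggplot2::geom_line(ggplot2::aes(colour = .data$region), alpha = 0.6)
  } else {
    p + ggplot2::geom_line(alpha = 0.6)
  }
  p + ggplot2::labs(x = "longitudinal position (µm)",
                    y = "height above BM (µm)",
                    title = "Type-2 fiber trajectories") +
    ggplot2::theme_minimal()
}

#' Innervation heat map
#'
#' Fibers by OHC targets, tile intensity = synapse count, columns ordered by
#' OHC row.
#'
#' @param imat an [innervation_matrix()].
#' @return a ggplot object.
#' @export
plot_innervation <- function(imat) {
  long <- as_tibble(as.table(imat$counts), .name_repair = "minimal")
  names(long) <- c("fiber_id", "target_id", "n")
  long$row <- imat$target_rows[long$target_id]
  long <- long |> filter(.data$n > 0)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$target_id, y = .data$fiber_id,
                                     fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(~row, scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "OHC (by row)", y = "fiber", fill = "synapses",
                  title = sprintf("%s innervation", imat$kind)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @exportS3Method ggplot2::autoplot
autoplot.innervation_matrix <- function(object, ...) plot_innervation(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
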
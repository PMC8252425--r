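#' Significance band for a p-value
#'
#' Band convention: `n.s.` for p > .05, `*` for p < .05, `**` for p < .01,
#' `***` for p < .001 (a p exactly on a threshold takes the weaker band).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return character vector of bands.
#' @examples
#' significance_band(c(0.2, 0.03, 0.004, 2e-5))
#' @export
significance_band <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "n.s."
  )
}

#' Compare groups of measurements
#'
#' Reporting utility wrapping the classical tests used for the figure-style
#' group comparisons: equal-variance two-sample t-test (Welch by flag), paired
#' t-test, and one-way ANOVA. Returns a broom-style one-row tibble with the
#' significance band. No multiple-testing correction is applied; pairwise
#' p-values are reported raw alongside any ANOVA, matching the reporting
#' convention this package mirrors.
#'
#' @param data data frame with a value column and a group column.
#' @param value,group column names (strings) of the measurement and grouping
#'   variable.
#' @param test `"two_sample_t"`, `"paired_t"` or `"one_way_anova"`.
#' @param var_equal classical equal-variance t-test (default `TRUE`); set
#'   `FALSE` for Welch.
#' @param alternative passed to [stats::t.test()] for t-tests.
#' @return tibble: `test, statistic, p_value, band`, plus per-group `n`,
#'   `mean`, `sd` in a nested `groups` column.
#' @export
compare_groups <- function(data, value, group,
                           test = c("two_sample_t", "paired_t", "one_way_anova"),
                           var_equal = TRUE, alternative = "two.sided") {
  test <- match.arg(test)
  v <- data[[value]]
  g <- factor(data[[group]])
  split_v <- split(v, g)
  ns <- map_int(split_v, length)
  if (any(ns < 2)) {
    abort(sprintf("group '%s' has fewer than 2 values",
                  names(split_v)[which(ns < 2)[1]]),
          class = "cortimorph_bad_input")
  }
  gr <- tibble(group = names(split_v), n = unname(ns),
               mean = map_dbl(split_v, mean), sd = map_dbl(split_v, sd))
  if (test == "two_sample_t" || test == "paired_t") {
    if (length(split_v) != 2) {
      abort(sprintf("%s needs exactly 2 groups", test),
            class = "cortimorph_bad_input")
    }
    if (test == "paired_t" && ns[1] != ns[2]) {
      abort("paired test requires equal-length paired vectors",
            class = "cortimorph_bad_input")
    }
    ht <- t.test(split_v[[1]], split_v[[2]],
                 paired = test == "paired_t",
                 var.equal = var_equal, alternative = alternative)
    stat <- unname(ht$statistic); p <- ht$p.value
  } else {
    fit <- aov(v ~ g)
    sm <- summary(fit)[[1]]
    stat <- sm[["F value"]][1]; p <- sm[["Pr(>F)"]][1]
  }
  tibble(test = test, statistic = stat, p_value = p,
         band = significance_band(p), groups = list(gr))
}

#' Paired one-sided test that climbing slopes exceed contact slopes
#'
#' @param fits list of `biphasic_fit` objects (fibers lacking a contact
#'   compartment are dropped).
#' @return one-row tibble from [compare_groups()].
#' @export
compare_slopes_paired <- function(fits) {
  tb <- bind_rows(map(fits, tidy)) |>
    tidyr::pivot_wider(id_cols = "fiber_id", names_from = "compartment",
                       values_from = "slope") |>
    filter(!is.na(.data$contact))
  dat <- tibble(value = c(tb$climbing, tb$contact),
                compartment = rep(c("climbing", "contact"), each = nrow(tb)))
  compare_groups(dat, "value", "compartment", test = "paired_t",
                 alternative = "greater")
}
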
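#' @keywords internal
"_PACKAGE"

#' @importFrom rlang %||% .data abort warn inform
#' @importFrom dplyr filter mutate select arrange group_by summarise ungroup
#'   bind_rows left_join n across pull row_number rename distinct slice
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map2 pmap map_dbl map_int map_chr map_lgl imap keep
#' @importFrom stats setNames rnorm runif qnorm pnorm dnorm sd t.test aov
#'   lm coef uniroot median complete.cases
#' @importFrom utils head tail
NULL

NM_PER_UM <- 1000

#' Normalize a 3-vector to unit length
#' @param v numeric length-3 vector.
#' @param tol tolerance under which a non-unit input is an error rather than
#'   silently rescaled.
#' @return unit vector.
#' @keywords internal
unitize <- function(v, tol = 1e-6) {
  stopifnot(length(v) == 3, all(is.finite(v)))
  nv <- sqrt(sum(v^2))
  if (nv == 0) abort("cannot normalize a zero vector", class = "cortimorph_degenerate")
  if (abs(nv - 1) > tol) {
    # tolerate mild drift but refuse garbage
    if (abs(nv - 1) > 0.1) {
      abort(sprintf("expected a unit vector, got |v| = %.4f", nv),
            class = "cortimorph_bad_input")
    }
    warn(sprintf("normalizing a non-unit vector (|v| = %.8f)", nv))
  }
  v / nv
}

#' Angle between two vectors in degrees
#' @keywords internal
angle_deg <- function(u, v) {
  u <- u / sqrt(sum(u^2))
  v <- v / sqrt(sum(v^2))
  d <- sum(u * v)
  d <- max(-1, min(1, d))
  acos(d) * 180 / pi
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Truncated-normal sampler (rejection-free, via CDF inversion)
#'
#' Used for all per-cell geometry draws; truncation keeps samples physical.
#' @param n number of draws.
#' @param mean,sd Gaussian parameters; `sd = 0` returns `mean` exactly.
#' @param lo,hi truncation bounds.
#' @return numeric vector of length `n`.
#' @keywords internal
rtruncnorm <- function(n, mean, sd, lo = mean - 4 * sd, hi = mean + 4 * sd) {
  if (sd <= 0) return(rep(mean, n))
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Discrete Gaussian over an integer range, location-calibrated
#'
#' Returns a probability table over `lo:hi` whose mean equals `target_mean`.
#' A plain discretized Gaussian truncated to the printed range is biased
#' (truncation pulls the mean inward), so the latent location is solved once
#' with [stats::uniroot()].
#' @param target_mean desired mean of the discrete distribution.
#' @param sd latent Gaussian scale.
#' @param lo,hi inclusive integer support.
#' @return tibble with columns `k`, `p`.
#' @keywords internal
calibrate_discrete_gaussian <- function(target_mean, sd, lo, hi) {
  ks <- lo:hi
  mean_at <- function(mu) {
    w <- dnorm(ks, mu, sd)
    sum(ks * w) / sum(w)
  }
  if (target_mean <= lo || target_mean >= hi) {
    abort("target mean must lie strictly inside the integer support")
  }
  mu <- uniroot(function(m) mean_at(m) - target_mean,
                lower = lo - 4 * sd, upper = hi + 4 * sd, tol = 1e-12)$root
  w <- dnorm(ks, mu, sd)
  tibble(k = ks, p = w / sum(w))
}

sample_discrete <- function(n, tab) {
  sample(tab$k, n, replace = TRUE, prob = tab$p)
}

#' Round a vector stochastically so the expectation is preserved
#' @keywords internal
stochastic_round <- function(x) {
  fl <- floor(x)
  as.integer(fl + (runif(length(x)) < (x - fl)))
}
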
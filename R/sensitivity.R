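#' Bottleneck sensitivity of rate estimates
#'
#' Ratio of the tag-frequency variance induced by a technical multinomial
#' sampling event of size `nb` to the variance generated by the birth-death
#' process itself:
#' \deqn{s_B(t) = \frac{r\,N(0)}{(\beta+\delta)(1-e^{-rt})\,N_B},}
#' with the limit `n0 / ((beta + delta) t nb)` at `|r| t < 1e-8`. Numerator
#' and denominator change sign together, so `s_B > 0` for all `r != 0`. Large
#' values mean technical sampling noise dominates biological drift, making
#' rate estimates fragile to errors in the bottleneck correction terms; values
#' above the empirically calibrated threshold 0.17 flag an experiment for
#' re-design (sample more cells, lower `N(0)`, or sample later).
#'
#' `n0` is a per-volume quantity; use the CFU count per ml.
#'
#' @inheritParams founder_theory
#' @param nb Technical bottleneck size (cells sampled or reads sequenced);
#'   `Inf` (unlimited depth) gives sensitivity 0.
#' @return Numeric vector of sensitivities (arguments recycle).
#' @examples
#' bottleneck_sensitivity(beta = 0.025, delta = 0, t = 20, n0 = 1.95e5, nb = 8.643e5)
#' @export
bottleneck_sensitivity <- function(beta, delta, t, n0, nb) {
  n <- max(length(beta), length(delta), length(t), length(n0), length(nb))
  beta <- rep_len(beta, n); delta <- rep_len(delta, n)
  t <- rep_len(t, n); n0 <- rep_len(n0, n); nb <- rep_len(nb, n)
  if (any(beta < 0) || any(delta < 0)) stop("rates must be >= 0.", call. = FALSE)
  if (any(beta + delta <= 0)) stop("`beta + delta` must be > 0.", call. = FALSE)
  if (any(t <= 0)) stop("`t` must be > 0.", call. = FALSE)
  if (any(nb <= 0)) stop("`nb` must be > 0.", call. = FALSE)
  r <- beta - delta
  limit <- abs(r) * t < RT_LIMIT
  out <- numeric(n)
  out[limit] <- n0[limit] / ((beta[limit] + delta[limit]) * t[limit] * nb[limit])
  i <- !limit
  out[i] <- r[i] * n0[i] / ((beta[i] + delta[i]) * (1 - exp(-r[i] * t[i])) * nb[i])
  out
}

#' Bottleneck sensitivity over a grid of plausible rates
#'
#' Evaluates [bottleneck_sensitivity()] over a grid of candidate division and
#' death rates, the experiment-design workflow for choosing sample sizes and
#' timepoints before measuring: bound the plausible rates (e.g. via
#' [rate_from_doubling_time()] on the fastest plausible doubling and halving
#' times), and check whether any grid cell exceeds the threshold.
#'
#' @param beta_range,delta_range Length-2 numeric ranges of rates (1/min).
#' @param step Grid increment (1/min), > 0.
#' @param t Sampling time (min).
#' @param n0 Census at time 0 (CFU per ml).
#' @param nb Technical bottleneck size.
#' @param threshold Sensitivity threshold; 0.17 is the empirically calibrated
#'   default.
#' @return A tibble with columns `beta`, `delta`, `s_b`, `exceeds`. Cells with
#'   `beta == delta == 0` are undefined and dropped.
#' @export
sensitivity_grid <- function(beta_range, delta_range, step, t, n0, nb,
                             threshold = 0.17) {
  check_positive(step, "step")
  grid <- tidyr::expand_grid(
    beta = seq(min(beta_range), max(beta_range), by = step),
    delta = seq(min(delta_range), max(delta_range), by = step)
  )
  grid <- dplyr::filter(grid, .data$beta + .data$delta > 0)
  grid$s_b <- bottleneck_sensitivity(grid$beta, grid$delta, t = t, n0 = n0, nb = nb)
  grid$exceeds <- grid$s_b > threshold
  attr(grid, "threshold") <- threshold
  grid
}

#' Plot a bottleneck-sensitivity grid
#'
#' @param grid A tibble from [sensitivity_grid()].
#' @param threshold Threshold drawn as a contour; defaults to the one stored
#'   on the grid.
#' @return A ggplot object: log10 sensitivity raster over the rate grid.
#' @export
plot_sensitivity_grid <- function(grid, threshold = attr(grid, "threshold") %||% 0.17) {
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$beta, y = .data$delta)) +
    ggplot2::geom_raster(ggplot2::aes(fill = log10(.data$s_b))) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$s_b), breaks = threshold,
                          colour = "red", linewidth = 0.4) +
    ggplot2::scale_fill_viridis_c(name = expression(log[10] ~ s[B])) +
    ggplot2::labs(x = expression(beta ~ (min^-1)), y = expression(delta ~ (min^-1)),
                  title = "Bottleneck sensitivity",
                  subtitle = paste("red contour: threshold", threshold)) +
    ggplot2::theme_minimal()
}
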
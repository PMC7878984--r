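#' Net growth rate from a CFU time series
#'
#' Ordinary least-squares fit of `ln(CFU/ml)` on time; the slope is the net
#' growth rate `r = beta - delta`, reported with its 95% confidence interval.
#'
#' @param data A data frame with columns `time_min` and `cfu_per_ml`
#'   (replicate rows at the same time are allowed and enter the fit
#'   individually).
#' @return An object of class `growth_rate_fit` wrapping the underlying
#'   [stats::lm()] fit; `tidy()` returns the coefficient table and `glance()`
#'   a one-row summary with `rate`, `conf.low`, `conf.high`.
#' @examples
#' cfu <- tibble::tibble(time_min = c(0, 30, 60), cfu_per_ml = 1e5 * exp(0.02 * c(0, 30, 60)))
#' glance(growth_rate(cfu))
#' @export
growth_rate <- function(data) {
  data <- tibble::as_tibble(data)
  if (!all(c("time_min", "cfu_per_ml") %in% names(data))) {
    stop("`data` must have `time_min` and `cfu_per_ml` columns.", call. = FALSE)
  }
  if (any(data$cfu_per_ml <= 0)) stop("all CFU values must be positive.", call. = FALSE)
  if (length(unique(data$time_min)) < 2L) stop("need at least 2 distinct timepoints.", call. = FALSE)
  fit <- stats::lm(log(cfu_per_ml) ~ time_min, data = data)
  ci <- if (stats::df.residual(fit) > 0) {
    suppressWarnings(stats::confint(fit, "time_min", level = 0.95))
  } else {
    matrix(NA_real_, 1, 2) # saturated fit: no residual df for a CI
  }
  structure(
    list(rate = unname(stats::coef(fit)[["time_min"]]),
         intercept = unname(stats::coef(fit)[["(Intercept)"]]),
         conf.low = ci[1, 1], conf.high = ci[1, 2],
         n = nrow(data), fit = fit),
    class = "growth_rate_fit"
  )
}

#' @export
print.growth_rate_fit <- function(x, ...) {
  cat("<growth_rate_fit> r =", format(x$rate, digits = 5), "min^-1  (95% CI",
      format(x$conf.low, digits = 5), "-", format(x$conf.high, digits = 5),
      "), n =", x$n, "\n")
  invisible(x)
}

#' @export
tidy.growth_rate_fit <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  new_tbl(term = rownames(co), estimate = co[, 1], std.error = co[, 2],
          statistic = co[, 3], p.value = co[, 4])
}

#' @export
glance.growth_rate_fit <- function(x, ...) {
  new_tbl(rate = x$rate, intercept = x$intercept,
          conf.low = x$conf.low, conf.high = x$conf.high,
          r.squared = summary(x$fit)$r.squared, n = x$n)
}

#' Division and death rates from founder size and census
#'
#' Inverts the closed-form mean founder size of a birth-death process to
#' recover the individual rates from three measured quantities: the net growth
#' rate `r`, the census sizes `N(0)` and `N(t)`, and the founder size
#' `N_B(t)`:
#' \deqn{\hat\delta = \frac{r}{2}\left[\frac{N(0)}
#'   {N_B(t)\,(1 - N(0)/N(t))} - 1\right], \qquad \hat\beta = r + \hat\delta.}
#' All inputs must refer to the same reference volume (see [scale_volume()]).
#' When the census did not change (`n0 == nt`, i.e. `r` is effectively 0) the
#' expression degenerates and the analytic limit
#' `delta = n0 / (2 nb t) - r / 2` is used, which requires `t`.
#'
#' @param r Net growth rate (1/min), e.g. from [growth_rate()].
#' @param n0,nt Census population sizes at time 0 and `t` (per ml).
#' @param nb Founder population size at `t` (per ml); either a number or a
#'   `founder_estimate`. A negative-flagged estimate is an error: it signals
#'   technical bottlenecks too stringent for rate estimation, and the
#'   experiment should be re-designed (larger samples, later timepoints).
#' @param t Elapsed time (min); only required in the `n0 == nt` limit.
#' @return An object of class `rate_estimate` with elements `beta_hat`,
#'   `delta_hat`, `r_hat` (satisfying `beta_hat - delta_hat == r_hat`) and the
#'   inputs as provenance; `tidy()` gives a one-row tibble.
#' @examples
#' nb <- founder_theory(0.01, 0.03, t = 120, n0 = 1e6)
#' rate_estimates(r = -0.02, n0 = 1e6, nt = 1e6 * exp(-2.4), nb = nb)
#' @export
rate_estimates <- function(r, n0, nt, nb, t = NULL) {
  if (inherits(nb, "founder_estimate")) {
    if (nb$negative_flag) {
      stop("founder estimate is negative-flagged: technical bottleneck corrections ",
           "exceed the observed drift. Re-design the experiment (larger sample sizes, ",
           "longer times) instead of estimating rates.", call. = FALSE)
    }
    nb <- nb$value
  }
  check_number(r, "r")
  check_positive(n0, "n0"); check_positive(nt, "nt")
  check_positive(nb, "nb")
  degenerate <- isTRUE(all.equal(n0, nt, tolerance = 1e-12))
  if (degenerate) {
    if (is.null(t)) {
      stop("census unchanged (n0 == nt): the r -> 0 limit needs the elapsed time `t`.",
           call. = FALSE)
    }
    check_positive(t, "t")
    delta <- n0 / (2 * nb * t) - r / 2
  } else {
    delta <- (r / 2) * (n0 / (nb * (1 - n0 / nt)) - 1)
  }
  beta <- r + delta
  structure(
    list(beta_hat = beta, delta_hat = delta, r_hat = r,
         n0 = n0, nt = nt, nb = nb, t = t),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat("<rate_estimate> beta =", format(x$beta_hat, digits = 5),
      " delta =", format(x$delta_hat, digits = 5),
      " r =", format(x$r_hat, digits = 5), "min^-1\n")
  invisible(x)
}

#' @export
tidy.rate_estimate <- function(x, ...) {
  new_tbl(beta_hat = x$beta_hat, delta_hat = x$delta_hat, r_hat = x$r_hat,
          n0 = x$n0, nt = x$nt, nb = x$nb)
}

#' @export
glance.rate_estimate <- function(x, ...) tidy.rate_estimate(x, ...)

#' Division and death rates from plasmid segregation
#'
#' Comparator method based on the exponential dilution of a conditionally
#' non-replicative plasmid: the plasmid-positive fraction decays as
#' `F(t) = F(0) exp(-beta t)`, so
#' \deqn{\beta = \frac{1}{t}\ln\frac{F(0)}{F(t)}, \qquad
#'       \delta = \frac{1}{t}\ln\frac{F(0)N(0)}{F(t)N(t)}.}
#'
#' @param data A data frame with columns `f0`, `ft` (plasmid-positive
#'   fractions in (0, 1], `ft > 0`), `n0`, `nt` (census sizes) and `t`
#'   (minutes, > 0); one row per observation.
#' @return A tibble with one row per observation: `beta_hat`, `delta_hat`,
#'   `r_hat` (`= beta_hat - delta_hat`).
#' @examples
#' plasmid_rates(tibble::tibble(f0 = 0.3, ft = 0.15, n0 = 1e5, nt = 2e5, t = 28))
#' @export
plasmid_rates <- function(data) {
  data <- tibble::as_tibble(data)
  need <- c("f0", "ft", "n0", "nt", "t")
  if (!all(need %in% names(data))) {
    stop("`data` must have columns ", paste(need, collapse = ", "), ".", call. = FALSE)
  }
  if (any(data$ft <= 0)) {
    stop("`ft` must be > 0: the plasmid marker is fully diluted and carries no signal.",
         call. = FALSE)
  }
  if (any(data$f0 <= 0 | data$f0 > 1 | data$ft > 1)) {
    stop("plasmid-positive fractions must lie in (0, 1].", call. = FALSE)
  }
  if (any(data$t <= 0)) stop("`t` must be > 0.", call. = FALSE)
  beta <- log(data$f0 / data$ft) / data$t
  delta <- log((data$f0 * data$n0) / (data$ft * data$nt)) / data$t
  new_tbl(beta_hat = beta, delta_hat = delta, r_hat = beta - delta,
          t = data$t)
}

#' Interconvert exponential rates and doubling/halving times
#'
#' `rate_from_doubling_time(15)` gives the division rate of a population that
#' doubles every 15 min (`ln 2 / 15`); the same reciprocal relation converts a
#' death rate to a halving time or a net growth rate to a generation time.
#'
#' @param minutes Doubling (or halving) time in minutes.
#' @param rate Exponential rate in 1/min.
#' @return A rate (1/min) or a time (min).
#' @export
rate_from_doubling_time <- function(minutes) {
  if (any(minutes <= 0)) stop("`minutes` must be > 0.", call. = FALSE)
  log(2) / minutes
}

#' @rdname rate_from_doubling_time
#' @export
doubling_time <- function(rate) {
  if (any(rate <= 0)) stop("`rate` must be > 0.", call. = FALSE)
  log(2) / rate
}
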
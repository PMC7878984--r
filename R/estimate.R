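#' Full rate-estimation pipeline over an experiment
#'
#' Ties the pieces together for a complete experiment: builds the mean
#' reference profile, fits the net growth rate to the CFU series, computes a
#' bottleneck-corrected, volume-scaled founder size per timepoint, recovers
#' the division and death rates, and (optionally) attaches the bottleneck
#' sensitivity per timepoint. Negative-flagged founder sizes and
#' above-threshold sensitivities produce warnings, not failures: both are
#' diagnostics of an experiment that should be re-designed, and the remaining
#' timepoints are still informative.
#'
#' @param timepoints Data frame with columns `tag`, `count`, `time_min` (one
#'   count table per timepoint; see [read_tag_counts()]).
#' @param reference Data frame with columns `tag`, `count` and optionally
#'   `replicate` (the time-0 samples), or a ready [reference_profile()].
#' @param cfu Data frame with `time_min`, `cfu_per_ml` (replicates allowed).
#'   Must include time 0 (otherwise the regression intercept is used for
#'   `N(0)`).
#' @param ledger Optional [bottleneck_ledger()].
#' @param measured_volume,reference_volume Volume the tag samples were taken
#'   from and the volume the CFU counts refer to (same units); founder sizes
#'   are rescaled by their ratio.
#' @param emulation_delta If the experiment emulated a death process by
#'   volume sampling, the emulated death rate; founder sizes are then scaled
#'   by `1/(1 - exp(-delta t))` per timepoint.
#' @param sensitivity_nb Technical bottleneck size(s) for the per-timepoint
#'   sensitivity (scalar or one per timepoint); `NULL` skips the column.
#' @param threshold Sensitivity warning threshold (default 0.17).
#' @return A tibble of class `rate_experiment` with one row per timepoint:
#'   `time_min`, `nb_raw`, `nb`, `negative_flag`, `cfu`, `beta_hat`,
#'   `delta_hat`, `r_hat`, and `s_b` when requested. Attributes: `growth_fit`
#'   (the [growth_rate()] object), `n0`, `volume_scale`.
#' @export
estimate_experiment <- function(timepoints, reference, cfu, ledger = NULL,
                                measured_volume = 1, reference_volume = 1,
                                emulation_delta = NULL, sensitivity_nb = NULL,
                                threshold = 0.17) {
  timepoints <- tibble::as_tibble(timepoints)
  if (!all(c("tag", "count", "time_min") %in% names(timepoints))) {
    stop("`timepoints` must have `tag`, `count` and `time_min` columns.", call. = FALSE)
  }
  ref <- if (is_reference_profile(reference)) reference else reference_profile(reference)
  fit <- growth_rate(cfu)
  r <- fit$rate

  cfu_mean <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(cfu), .data$time_min),
                               cfu = mean(.data$cfu_per_ml), .groups = "drop")
  n0 <- if (any(cfu_mean$time_min == 0)) {
    cfu_mean$cfu[cfu_mean$time_min == 0]
  } else {
    exp(fit$intercept)
  }

  times <- sort(unique(timepoints$time_min))
  if (!is.null(sensitivity_nb)) sensitivity_nb <- rep_len(sensitivity_nb, length(times))

  rows <- purrr::map_dfr(seq_along(times), function(i) {
    tt <- times[i]
    est <- founder_size(dplyr::filter(timepoints, .data$time_min == tt), ref, ledger)
    est <- scale_volume(est, measured_volume, reference_volume)
    if (!is.null(emulation_delta) && !est$negative_flag) {
      est <- scale_death_emulation(est, emulation_delta, tt)
    }
    nt <- if (any(cfu_mean$time_min == tt)) {
      cfu_mean$cfu[cfu_mean$time_min == tt]
    } else {
      exp(fit$intercept + r * tt)
    }
    if (est$negative_flag) {
      warning("timepoint ", tt, " min: corrected founder size is non-positive; ",
              "technical bottlenecks dominate the drift signal here.", call. = FALSE)
      rates <- list(beta_hat = NA_real_, delta_hat = NA_real_, r_hat = r)
    } else {
      rates <- rate_estimates(r = r, n0 = n0, nt = nt, nb = est, t = tt)
    }
    out <- new_tbl(time_min = tt, nb_raw = est$raw_value, nb = est$value,
                   negative_flag = est$negative_flag, cfu = nt,
                   beta_hat = rates$beta_hat, delta_hat = rates$delta_hat,
                   r_hat = rates$r_hat)
    if (!is.null(sensitivity_nb)) {
      # sensitivity needs non-negative rates; noisy estimates are clamped at 0
      b <- max(rates$beta_hat %||% NA_real_, 0, na.rm = TRUE)
      d <- max(rates$delta_hat, 0, na.rm = TRUE)
      out$s_b <- if (is.finite(b + d) && b + d > 0) {
        bottleneck_sensitivity(b, d, t = tt, n0 = n0, nb = sensitivity_nb[i])
      } else {
        NA_real_
      }
    }
    out
  })

  if (!is.null(sensitivity_nb) && any(rows$s_b > threshold, na.rm = TRUE)) {
    warning("bottleneck sensitivity exceeds ", threshold, " at timepoint(s) ",
            paste(rows$time_min[which(rows$s_b > threshold)], collapse = ", "),
            " min; rate estimates there are fragile to correction errors.",
            call. = FALSE)
  }

  attr(rows, "growth_fit") <- fit
  attr(rows, "n0") <- n0
  attr(rows, "volume_scale") <- reference_volume / measured_volume
  class(rows) <- c("rate_experiment", class(rows))
  rows
}

#' @export
glance.rate_experiment <- function(x, ...) {
  fit <- attr(x, "growth_fit")
  new_tbl(
    r = fit$rate, r_conf.low = fit$conf.low, r_conf.high = fit$conf.high,
    n0 = attr(x, "n0"),
    mean_beta_hat = mean(x$beta_hat, na.rm = TRUE),
    mean_delta_hat = mean(x$delta_hat, na.rm = TRUE),
    n_timepoints = nrow(x),
    n_negative = sum(x$negative_flag)
  )
}

#' @export
autoplot.rate_experiment <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("beta_hat", "delta_hat"),
                              names_to = "rate", values_to = "estimate")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_min, y = .data$estimate,
                                     colour = .data$rate)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = attr(object, "growth_fit")$rate,
                        linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "time (min)", y = expression(rate ~ (min^-1)),
                  title = "Per-timepoint division and death rate estimates",
                  subtitle = "dashed line: net growth rate") +
    ggplot2::theme_minimal()
}
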
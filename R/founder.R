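#' Bottleneck ledger
#'
#' Records the technical sampling events (pipetting, limited sequencing depth)
#' an experiment imposes on the time-zero (inoculum-side) and timepoint
#' (sample-side) samples. Each stage is one sampling event; replicate
#' measurements of a stage's sample size are averaged as the mean of their
#' inverses, which is the quantity the analytic correction subtracts.
#'
#' @param inoculum,sample Lists (or numeric vectors) of sample sizes, one
#'   element per sequential sampling stage; an element may be a vector of
#'   replicate sizes. `NULL` or empty means no corrections on that side.
#' @return An object of class `bottleneck_ledger` with elements
#'   `inoculum_inverse_means` and `sample_inverse_means`.
#' @examples
#' bottleneck_ledger(inoculum = c(1e6, 1e6), sample = c(1e5, 1e6))
#' @export
bottleneck_ledger <- function(inoculum = NULL, sample = NULL) {
  inv_means <- function(x, side) {
    if (is.null(x) || length(x) == 0L) return(numeric(0))
    if (!is.list(x)) x <- as.list(x)
    vapply(x, function(sizes) {
      if (any(is.na(sizes)) || any(sizes <= 0)) {
        stop("all ", side, " sample sizes must be positive.", call. = FALSE)
      }
      mean(1 / sizes)
    }, numeric(1))
  }
  structure(
    list(inoculum_inverse_means = inv_means(inoculum, "inoculum"),
         sample_inverse_means = inv_means(sample, "sample")),
    class = "bottleneck_ledger"
  )
}

#' @export
print.bottleneck_ledger <- function(x, ...) {
  cat("<bottleneck_ledger>\n")
  cat("  inoculum-side <I_j^-1>:", format(x$inoculum_inverse_means, digits = 4), "\n")
  cat("  sample-side   <S_j^-1>:", format(x$sample_inverse_means, digits = 4), "\n")
  invisible(x)
}

ledger_inverse_sum <- function(ledger) {
  if (is.null(ledger)) return(0)
  if (!inherits(ledger, "bottleneck_ledger")) {
    stop("`ledger` must be a bottleneck_ledger (see `bottleneck_ledger()`).", call. = FALSE)
  }
  sum(ledger$inoculum_inverse_means) + sum(ledger$sample_inverse_means)
}

#' Founder population size from tag-frequency drift
#'
#' Aggregates the drift of per-tag frequencies between a timepoint sample and
#' the mean time-zero reference into a single founder population size: the size
#' of a hypothetical population whose multinomial sampling noise would produce
#' the observed frequency change. The estimate is the inverse of the mean
#' standardized squared frequency deviation,
#' \deqn{N_B(t) = 1 / \left[\frac{1}{k}\sum_i
#'   \frac{(f_i(t) - \langle f_i(0)\rangle)^2}
#'        {\langle f_i(0)\rangle(1 - \langle f_i(0)\rangle)}\right].}
#' A small founder size signals a stringent bottleneck (biological or
#' technical).
#'
#' When a [bottleneck_ledger()] is supplied, the mean inverse sample sizes of
#' all technical sampling stages are subtracted from the inverse founder size
#' before inverting, removing the spurious drift those stages added. An
#' over-corrected (non-positive) denominator is returned flagged rather than
#' as an error: it is itself a diagnostic of very stringent technical
#' bottlenecks.
#'
#' @param data Timepoint sample: a data frame accepted by [tag_profile()].
#' @param reference A [reference_profile()], or a data frame coerced to one.
#'   Tag sets must match after dropping reference tags with frequency 0 or 1.
#' @param ledger Optional [bottleneck_ledger()] of technical corrections.
#' @return An object of class `founder_estimate`; see [tidy.founder_estimate()].
#' @examples
#' ref <- reference_profile(tibble::tibble(tag = c("a", "b"), count = c(50, 50)))
#' founder_size(tibble::tibble(tag = c("a", "b"), count = c(60, 40)), ref)
#' @export
founder_size <- function(data, reference, ledger = NULL) {
  profile <- tag_profile(data)
  if (!is_reference_profile(reference)) reference <- reference_profile(reference)
  if (!setequal(profile$tag, reference$tag)) {
    stop("timepoint and reference profiles carry different tag sets.", call. = FALSE)
  }
  ref <- reference[match(profile$tag, reference$tag), ]
  keep <- !ref$excluded
  k_used <- sum(keep)
  if (k_used < 2L) stop("fewer than 2 usable tags after excluding degenerate reference frequencies.", call. = FALSE)

  f_t <- profile$freq[keep]
  f_0 <- ref$mean_freq[keep]
  terms <- (f_t - f_0)^2 / (f_0 * (1 - f_0))
  d_raw <- mean(terms)

  correction <- ledger_inverse_sum(ledger)
  d_corr <- d_raw - correction
  value <- if (d_corr == 0) Inf else 1 / d_corr

  structure(
    list(
      value = value,
      raw_value = if (d_raw == 0) Inf else 1 / d_raw,
      denominator = d_corr,
      raw_denominator = d_raw,
      corrected = correction > 0,
      correction = correction,
      negative_flag = d_corr <= 0,
      identical_profiles = d_raw == 0,
      volume_scale = 1,
      emulation_scale = 1,
      k_used = k_used,
      n_excluded = sum(!keep),
      excluded_tags = ref$tag[!keep]
    ),
    class = "founder_estimate"
  )
}

#' @export
print.founder_estimate <- function(x, ...) {
  cat("<founder_estimate>\n")
  cat("  N_B:", format(x$value, digits = 6),
      if (x$corrected) "(bottleneck-corrected)" else "(uncorrected)", "\n")
  if (x$negative_flag) {
    cat("  WARNING: non-positive corrected denominator -- corrections exceed the\n",
        " observed drift; this indicates very stringent technical bottlenecks.\n")
  }
  if (x$volume_scale != 1) cat("  volume scale:", x$volume_scale, "\n")
  if (x$emulation_scale != 1) cat("  death-emulation scale:", x$emulation_scale, "\n")
  cat("  tags used:", x$k_used,
      if (x$n_excluded > 0) paste0("(", x$n_excluded, " excluded)") else "", "\n")
  invisible(x)
}

#' Tidy a founder estimate
#'
#' @param x A `founder_estimate` from [founder_size()].
#' @param ... Unused.
#' @return A one-row tibble with the estimate, flags and scaling metadata.
#' @export
tidy.founder_estimate <- function(x, ...) {
  new_tbl(
    founder_size = x$value,
    raw_founder_size = x$raw_value,
    corrected = x$corrected,
    negative_flag = x$negative_flag,
    volume_scale = x$volume_scale,
    emulation_scale = x$emulation_scale,
    k_used = x$k_used,
    n_excluded = x$n_excluded
  )
}

#' @export
glance.founder_estimate <- function(x, ...) tidy.founder_estimate(x, ...)

#' Theoretical mean founder population size of a birth-death process
#'
#' Closed-form ensemble mean of the founder size after cells divide at rate
#' `beta` and die at rate `delta` for `t` minutes starting from `n0` cells:
#' \deqn{\langle N_B(t)\rangle = \frac{(\beta-\delta)N(0)}
#'   {(\beta+\delta)(1 - e^{-(\beta-\delta)t})}.}
#' The mean is independent of the tag distribution, so an arbitrary number of
#' arbitrarily skewed tags can be aggregated. Near `beta == delta` the
#' expression degenerates to 0/0 and the analytic limit
#' `n0 / ((beta + delta) t)` is used (switch at `|r| t < 1e-8`).
#'
#' @param beta,delta Division and death rates (1/min), both >= 0 with
#'   `beta + delta > 0`.
#' @param t Elapsed time (min), > 0.
#' @param n0 Initial census size (cells per reference volume), > 0.
#' @return Numeric vector of mean founder sizes (arguments recycle).
#' @examples
#' founder_theory(beta = 0.01, delta = 0.03, t = 120, n0 = 1e6)
#' @export
founder_theory <- function(beta, delta, t, n0) {
  n <- max(length(beta), length(delta), length(t), length(n0))
  beta <- rep_len(beta, n); delta <- rep_len(delta, n)
  t <- rep_len(t, n); n0 <- rep_len(n0, n)
  if (any(beta < 0) || any(delta < 0)) stop("rates must be >= 0.", call. = FALSE)
  if (any(beta + delta <= 0)) stop("`beta + delta` must be > 0.", call. = FALSE)
  if (any(t <= 0)) stop("`t` must be > 0 (the founder size is undefined at t = 0).", call. = FALSE)
  if (any(n0 <= 0)) stop("`n0` must be > 0.", call. = FALSE)
  r <- beta - delta
  limit <- abs(r) * t < RT_LIMIT
  out <- numeric(n)
  out[limit] <- n0[limit] / ((beta[limit] + delta[limit]) * t[limit])
  i <- !limit
  out[i] <- r[i] * n0[i] / ((beta[i] + delta[i]) * (1 - exp(-r[i] * t[i])))
  out
}

#' Variance of a tag's frequency under a birth-death process
#'
#' Error-propagation approximation to the across-replicate variance of the
#' proportion of cells carrying one tag after time `t`:
#' \deqn{Var(f_i(t)) \approx \frac{(\beta+\delta)(1-e^{-rt})}{r\,N(0)}
#'   f_i(0)(1-f_i(0)), \quad r = \beta - \delta,}
#' with the limit `(beta + delta) t / n0 * f0 (1 - f0)` at `|r| t < 1e-8`.
#'
#' @inheritParams founder_theory
#' @param f0 Initial frequency of the tag, in (0, 1).
#' @return Numeric vector of variances (arguments recycle).
#' @export
bd_freq_variance <- function(beta, delta, t, n0, f0) {
  n <- max(length(beta), length(delta), length(t), length(n0), length(f0))
  beta <- rep_len(beta, n); delta <- rep_len(delta, n)
  t <- rep_len(t, n); n0 <- rep_len(n0, n); f0 <- rep_len(f0, n)
  if (any(f0 <= 0 | f0 >= 1)) stop("`f0` must lie strictly in (0, 1).", call. = FALSE)
  if (any(n0 <= 0)) stop("`n0` must be > 0.", call. = FALSE)
  r <- beta - delta
  limit <- abs(r) * t < RT_LIMIT
  out <- numeric(n)
  out[limit] <- (beta[limit] + delta[limit]) * t[limit] / n0[limit]
  i <- !limit
  out[i] <- (beta[i] + delta[i]) * (1 - exp(-r[i] * t[i])) / (r[i] * n0[i])
  out * f0 * (1 - f0)
}

#' Rescale a founder estimate to the CFU reference volume
#'
#' Founder sizes are per-volume quantities: if the census is counted per ml but
#' tags were sequenced from 200 ul, the measured founder size must be
#' multiplied by 5 before rate estimation. The applied factor is recorded in
#' the estimate's `volume_scale`, and rescalings compose multiplicatively.
#'
#' @param x A `founder_estimate`.
#' @param measured_volume Volume the tag sample was taken from.
#' @param reference_volume Volume the census (CFU) refers to (same units).
#' @return The rescaled `founder_estimate`.
#' @export
scale_volume <- function(x, measured_volume, reference_volume) {
  stopifnot(inherits(x, "founder_estimate"))
  check_positive(measured_volume, "measured_volume")
  check_positive(reference_volume, "reference_volume")
  factor <- reference_volume / measured_volume
  x$value <- x$value * factor
  x$raw_value <- x$raw_value * factor
  x$volume_scale <- x$volume_scale * factor
  x
}

#' Scale a founder estimate from a death-emulation sampling experiment
#'
#' A pure death process with rate `delta` can be emulated by sampling a shrunk
#' volume (see [death_emulation_volumes()]), but the sampling variance differs
#' from the true death-process variance by the factor `1 - p` with
#' `p = exp(-delta t)` (the single-cell survival probability). Matching the
#' two requires multiplying the measured founder size by `1 / (1 - p)`.
#'
#' @param x A `founder_estimate`.
#' @param delta Emulated death rate (1/min).
#' @param t Emulated time point (min). `delta * t` must be > 0, otherwise the
#'   factor diverges.
#' @return The scaled `founder_estimate`, with `emulation_scale` recorded.
#' @export
scale_death_emulation <- function(x, delta, t) {
  stopifnot(inherits(x, "founder_estimate"))
  check_number(delta, "delta", lower = 0)
  check_number(t, "t", lower = 0)
  if (delta * t <= 0) {
    stop("`delta * t` must be > 0: at t = 0 nothing was emulated and the scale factor diverges.",
         call. = FALSE)
  }
  factor <- 1 / (1 - exp(-delta * t))
  x$value <- x$value * factor
  x$raw_value <- x$raw_value * factor
  x$emulation_scale <- x$emulation_scale * factor
  x
}
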
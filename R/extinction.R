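#' Expected fraction of tags surviving a birth-death process
#'
#' Forecasts tag-library attrition: for a tag founded by `n0` cells, the
#' probability that its whole lineage is extinct by time `t` under a linear
#' birth-death process is
#' \deqn{p_{ext}(t) = \left[\frac{\delta(e^{rt}-1)}{\beta e^{rt}-\delta}\right]^{n_0}}
#' (with the limit `[delta t / (1 + delta t)]^(n0)` at `beta == delta`). The
#' expected surviving fraction is the mean of `1 - p_ext` over tags. Used at
#' the design stage to decide whether the library needs more tags before an
#' experiment with substantial death (set `delta ~ r` for a dying population).
#'
#' @param counts Initial cells per tag: an integer vector, or a data frame
#'   with a `count` column (e.g. from [geometric_library()]).
#' @param beta,delta Division and death rates (1/min), >= 0.
#' @param t Elapsed times (min); may be a vector.
#' @return A tibble with one row per `t`: `time_min`, `fraction_surviving`,
#'   `expected_tags` (`= k * fraction`), `k`.
#' @examples
#' expected_surviving_tags(rep(1, 1000), beta = 0, delta = 0.03, t = 120)
#' @export
expected_surviving_tags <- function(counts, beta, delta, t) {
  if (is.data.frame(counts)) counts <- counts$count
  if (any(counts < 0) || length(counts) == 0L) {
    stop("`counts` must be non-negative initial cells per tag.", call. = FALSE)
  }
  check_number(beta, "beta", lower = 0)
  check_number(delta, "delta", lower = 0)
  k <- length(counts)
  purrr::map_dfr(as.numeric(t), function(tt) {
    if (tt < 0) stop("`t` must be >= 0.", call. = FALSE)
    p_ext_one <- if (delta == 0) {
      0
    } else if (abs(beta - delta) * tt < RT_LIMIT) {
      delta * tt / (1 + delta * tt)
    } else {
      r <- beta - delta
      delta * (exp(r * tt) - 1) / (beta * exp(r * tt) - delta)
    }
    surv <- 1 - p_ext_one^counts # tags founded by 0 cells are already extinct
    frac <- mean(surv)
    new_tbl(time_min = tt, fraction_surviving = frac,
            expected_tags = k * frac, k = k)
  })
}
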
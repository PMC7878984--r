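#' Sampling volumes that emulate a pure death process
#'
#' A death process with rate `delta` leaves `N(0) exp(-delta t)` cells at time
#' `t`; the same census reduction is produced, without waiting, by sampling the
#' shrunk volume `v_t = v0 exp(-delta t)` from a well-mixed culture. The
#' emulated timepoints let the target death rate be chosen a priori, which is
#' how estimator accuracy is validated against a known truth. (The founder
#' size measured in such a sample must additionally be scaled; see
#' [scale_death_emulation()].)
#'
#' @param v0 Volume corresponding to time 0 (microliters), > 0.
#' @param delta Target death rate (1/min), >= 0.
#' @param times Emulated timepoints (min), >= 0.
#' @return A tibble with columns `time_min` and `volume_ul`.
#' @examples
#' death_emulation_volumes(100, 0.015, c(0, 20, 25, 30, 35, 40))
#' @export
death_emulation_volumes <- function(v0, delta, times) {
  check_positive(v0, "v0")
  check_number(delta, "delta", lower = 0)
  if (any(times < 0)) stop("`times` must be >= 0.", call. = FALSE)
  new_tbl(time_min = as.numeric(times), volume_ul = v0 * exp(-delta * times))
}
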
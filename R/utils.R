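# internal helpers shared across the package

`%||%` <- function(x, y) if (is.null(x)) y else x

# scalar numeric check used by argument validators
check_number <- function(x, name, lower = -Inf, upper = Inf, allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop("`", name, "` must be a single non-missing number.", call. = FALSE)
  }
  if (!allow_inf && !is.finite(x)) {
    stop("`", name, "` must be finite.", call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop("`", name, "` must be in [", lower, ", ", upper, "].", call. = FALSE)
  }
  invisible(x)
}

check_positive <- function(x, name) {
  check_number(x, name)
  if (x <= 0) stop("`", name, "` must be > 0.", call. = FALSE)
  invisible(x)
}

# relative-rate degeneracy guard: below this |r| * t the closed forms switch
# to their analytic r -> 0 limits to avoid 0/0
RT_LIMIT <- 1e-8

new_tbl <- function(...) tibble::tibble(...)
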
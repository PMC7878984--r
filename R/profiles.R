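#' Tag frequency profiles
#'
#' A tag frequency profile records, for one sample, the proportion of cells (or
#' sequence reads) carrying each neutral sequence tag. `tag_profile()` validates
#' a table of per-tag counts (or frequencies) and normalizes it; it is the
#' common currency consumed by [founder_size()].
#'
#' @param data A data frame with a `tag` column and either a `count` column
#'   (non-negative; converted to proportions) or a `freq` column (must sum to 1
#'   within `1e-9`).
#' @return A tibble with columns `tag`, `count` (`NA` if frequencies were
#'   supplied directly) and `freq`, carrying the attribute `total_count`.
#' @examples
#' tag_profile(tibble::tibble(tag = c("a", "b"), count = c(60, 40)))
#' @export
tag_profile <- function(data) {
  data <- tibble::as_tibble(data)
  if (!"tag" %in% names(data)) stop("`data` must have a `tag` column.", call. = FALSE)
  if (anyDuplicated(data$tag)) stop("duplicated tag ids in profile.", call. = FALSE)
  if (nrow(data) < 2L) stop("a tag profile needs at least 2 tags.", call. = FALSE)
  if ("count" %in% names(data)) {
    if (any(is.na(data$count)) || any(data$count < 0)) {
      stop("`count` must be non-negative and non-missing.", call. = FALSE)
    }
    total <- sum(data$count)
    if (total <= 0) stop("profile has zero total count.", call. = FALSE)
    out <- new_tbl(tag = as.character(data$tag), count = as.numeric(data$count),
                   freq = data$count / total)
  } else if ("freq" %in% names(data)) {
    if (any(data$freq < 0 | data$freq > 1)) {
      stop("`freq` values must lie in [0, 1].", call. = FALSE)
    }
    if (abs(sum(data$freq) - 1) > 1e-9) {
      stop("`freq` must sum to 1 (tolerance 1e-9).", call. = FALSE)
    }
    total <- NA_real_
    out <- new_tbl(tag = as.character(data$tag), count = NA_real_, freq = as.numeric(data$freq))
  } else {
    stop("`data` must have a `count` or a `freq` column.", call. = FALSE)
  }
  attr(out, "total_count") <- total
  out
}

#' Reference (time-zero) tag profile
#'
#' Averages the per-tag frequencies of one or more replicate time-zero samples
#' into the mean initial proportions used as the drift reference. Tags whose
#' mean reference frequency is exactly 0 (or 1) cannot contribute to the
#' founder-size sum; they are kept in the table but flagged in the `excluded`
#' column and reported by [founder_size()].
#'
#' @param data A data frame with columns `tag`, `count` (or `freq`) and
#'   optionally `replicate`. With a `replicate` column, frequencies are computed
#'   within each replicate and then averaged per tag; replicates may not all
#'   contain every tag, in which case missing tags count as frequency 0.
#' @return A tibble of class `reference_profile` with columns `tag`,
#'   `mean_freq`, `excluded`, and attribute `n_replicates`.
#' @export
reference_profile <- function(data) {
  data <- tibble::as_tibble(data)
  if (!"tag" %in% names(data)) stop("`data` must have a `tag` column.", call. = FALSE)
  if (!"replicate" %in% names(data)) data$replicate <- 1L
  reps <- split(data[setdiff(names(data), "replicate")], data$replicate)
  tags <- sort(unique(as.character(data$tag)))
  freq_mat <- vapply(reps, function(d) {
    p <- tag_profile(d)
    f <- stats::setNames(rep(0, length(tags)), tags)
    f[p$tag] <- p$freq
    f
  }, numeric(length(tags)))
  mean_freq <- rowMeans(as.matrix(freq_mat))
  out <- new_tbl(tag = tags, mean_freq = unname(mean_freq),
                 excluded = mean_freq <= 0 | mean_freq >= 1)
  attr(out, "n_replicates") <- length(reps)
  class(out) <- c("reference_profile", class(out))
  out
}

is_reference_profile <- function(x) inherits(x, "reference_profile")
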
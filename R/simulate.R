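#' Geometric tag library
#'
#' Draws the initial cells-per-tag counts of a tagged library from a geometric
#' distribution on support \{1, 2, ...\} (every constructed clone exists, so no
#' tag starts empty). With `k = 1000` and `prob = 1/1000` the expected census
#' is about 10^6 cells, a strongly skewed but realistic library.
#'
#' @param k Number of distinct tags.
#' @param prob Geometric probability parameter in (0, 1); mean cells per tag
#'   is `1 / prob`.
#' @param seed Optional integer seed.
#' @return A tibble with columns `tag` and `count`.
#' @export
geometric_library <- function(k, prob, seed = NULL) {
  check_positive(k, "k")
  check_number(prob, "prob")
  if (prob <= 0 || prob >= 1) stop("`prob` must lie in (0, 1).", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  new_tbl(tag = sprintf("tag%0*d", nchar(as.character(k)), seq_len(k)),
          count = stats::rgeom(k, prob) + 1)
}

as_count_matrix <- function(init, n_reps) {
  if (is.data.frame(init)) {
    tags <- as.character(init$tag %||% seq_len(nrow(init)))
    counts <- as.numeric(init$count)
  } else {
    tags <- names(init) %||% as.character(seq_along(init))
    counts <- as.numeric(init)
  }
  if (any(counts < 0) || any(is.na(counts))) stop("initial counts must be >= 0.", call. = FALSE)
  m <- matrix(counts, nrow = length(counts), ncol = n_reps)
  rownames(m) <- tags
  m
}

#' Tau-leaping birth-death simulation of a tagged library
#'
#' Simulates `n_reps` independent replicates of `k` tagged subpopulations,
#' each cell dividing at rate `beta` and dying at rate `delta`. Per fixed step
#' `dt`, births and deaths per tag are Poisson with means `beta * n * dt` and
#' `delta * n * dt`; deaths are capped at the current count so populations
#' never go negative, and extinct tags stay extinct. All replicates advance in
#' one vectorized matrix, so 100 replicates of 1000 tags cost little more than
#' one.
#'
#' Optional per-tag rate heterogeneity: with `rate_sd > 0`, each tag in each
#' replicate draws its own `(beta_i, delta_i)` once at time 0 from normal
#' distributions centred on `beta` and `delta` (truncated at 0) and keeps them
#' for the whole run.
#'
#' @param init Initial cells per tag: a data frame with `tag`/`count` columns
#'   (e.g. [geometric_library()]) or a named numeric vector.
#' @param beta,delta Division and death rates (1/min), >= 0.
#' @param t End time (min).
#' @param dt Leap step (min); must be small relative to `1/(beta + delta)`.
#' @param n_reps Number of replicate trajectories.
#' @param record_times Times at which to record the census (snapped to the
#'   step grid); final counts are always kept. Default: 13 evenly spaced times.
#' @param rate_sd Standard deviation of per-tag rate heterogeneity (1/min);
#'   0 (default) gives identical rates for all tags.
#' @param record_counts If `TRUE`, keep the full per-tag count matrix at every
#'   recorded time (list of `k x n_reps` matrices), not just the census.
#' @param seed Optional integer seed.
#' @return An object of class `bd_simulation`: list with `census` (tibble:
#'   `time`, `rep`, `census`), `final_counts` (`k x n_reps` matrix),
#'   `counts` (list, only if `record_counts`), `init`, and the parameters.
#' @examples
#' lib <- geometric_library(50, 1 / 50, seed = 1)
#' sim <- simulate_bd(lib, beta = 0.01, delta = 0.03, t = 60, n_reps = 5, seed = 2)
#' tidy(sim)
#' @export
simulate_bd <- function(init, beta, delta, t, dt = 0.01, n_reps = 1,
                        record_times = NULL, rate_sd = 0,
                        record_counts = FALSE, seed = NULL) {
  check_number(beta, "beta", lower = 0)
  check_number(delta, "delta", lower = 0)
  check_number(t, "t", lower = 0)
  check_positive(dt, "dt")
  check_positive(n_reps, "n_reps")
  check_number(rate_sd, "rate_sd", lower = 0)
  if ((beta + delta) * dt > 0.1) {
    warning("`dt` is large relative to 1/(beta + delta); tau-leap bias may be noticeable.")
  }
  if (!is.null(seed)) set.seed(seed)

  counts <- as_count_matrix(init, n_reps)
  k <- nrow(counts)
  n_steps <- as.integer(round(t / dt))
  record_times <- sort(unique(c(0, record_times %||% seq(0, t, length.out = 13L), t)))
  record_steps <- pmin(pmax(as.integer(round(record_times / dt)), 0L), n_steps)
  keep_unique <- !duplicated(record_steps)
  record_times <- record_times[keep_unique]
  record_steps <- record_steps[keep_unique]

  if (rate_sd > 0) {
    lam_b <- pmax(stats::rnorm(k * n_reps, beta, rate_sd), 0) * dt
    lam_d <- pmax(stats::rnorm(k * n_reps, delta, rate_sd), 0) * dt
  } else {
    lam_b <- beta * dt
    lam_d <- delta * dt
  }

  census <- matrix(NA_real_, nrow = length(record_steps), ncol = n_reps)
  snapshots <- if (record_counts) vector("list", length(record_steps)) else NULL
  rec <- function(idx) {
    census[idx, ] <<- colSums(counts)
    if (record_counts) snapshots[[idx]] <<- counts
  }
  hit <- match(0L, record_steps)
  if (!is.na(hit)) rec(hit)

  len <- k * n_reps
  for (s in seq_len(n_steps)) {
    births <- stats::rpois(len, counts * lam_b)
    deaths <- pmin(stats::rpois(len, counts * lam_d), counts)
    counts <- counts + births - deaths
    dim(counts) <- c(k, n_reps)
    hit <- match(s, record_steps)
    if (!is.na(hit)) rec(hit)
  }
  rownames(counts) <- rownames(as_count_matrix(init, 1L))

  structure(
    list(
      census = new_tbl(
        time = rep(record_times, times = n_reps),
        rep = rep(seq_len(n_reps), each = length(record_times)),
        census = as.vector(census)
      ),
      final_counts = counts,
      counts = snapshots,
      record_times = record_times,
      init = init,
      params = list(beta = beta, delta = delta, t = t, dt = dt,
                    n_reps = n_reps, rate_sd = rate_sd)
    ),
    class = "bd_simulation"
  )
}

#' @export
print.bd_simulation <- function(x, ...) {
  p <- x$params
  cat("<bd_simulation>", nrow(x$final_counts), "tags x", p$n_reps, "reps,",
      "beta =", p$beta, "delta =", p$delta, "t =", p$t, "dt =", p$dt, "\n")
  fin <- colSums(x$final_counts)
  cat("  final census: mean", format(mean(fin), digits = 5),
      "sd", format(stats::sd(fin), digits = 4), "\n")
  invisible(x)
}

#' @export
tidy.bd_simulation <- function(x, ...) x$census

#' @export
glance.bd_simulation <- function(x, ...) {
  fin <- colSums(x$final_counts)
  new_tbl(n_reps = x$params$n_reps, t = x$params$t,
          mean_census = mean(fin), sd_census = stats::sd(fin),
          mean_tags_alive = mean(colSums(x$final_counts > 0)))
}

#' @export
autoplot.bd_simulation <- function(object, ...) {
  cs <- dplyr::summarise(dplyr::group_by(object$census, .data$time),
                         mean = mean(.data$census), sd = stats::sd(.data$census),
                         .groups = "drop")
  ggplot2::ggplot(cs, ggplot2::aes(x = .data$time, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd), alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (min)", y = "census (cells)",
                  title = "Simulated census, ensemble mean ± SD") +
    ggplot2::theme_minimal()
}

#' Exact event-driven birth-death simulation
#'
#' Gillespie (stochastic simulation algorithm) reference implementation for
#' small instances: every division and death is an individual exponential
#' event. Exact but slow; used as the independent check of the tau-leaping
#' simulator and of the closed-form moments.
#'
#' @inheritParams simulate_bd
#' @return A `k x n_reps` matrix of final counts (rows named by tag).
#' @export
simulate_bd_exact <- function(init, beta, delta, t, n_reps = 1, seed = NULL) {
  check_number(beta, "beta", lower = 0)
  check_number(delta, "delta", lower = 0)
  check_number(t, "t", lower = 0)
  if (!is.null(seed)) set.seed(seed)
  counts <- as_count_matrix(init, n_reps)
  k <- nrow(counts)
  p_birth <- if (beta + delta > 0) beta / (beta + delta) else 0
  for (rep in seq_len(n_reps)) {
    n <- counts[, rep]
    time <- 0
    total <- sum(n)
    while (total > 0) {
      time <- time + stats::rexp(1, (beta + delta) * total)
      if (time > t) break
      i <- sample.int(k, 1L, prob = n)
      if (stats::runif(1) < p_birth) {
        n[i] <- n[i] + 1
        total <- total + 1
      } else {
        n[i] <- n[i] - 1
        total <- total - 1
      }
    }
    counts[, rep] <- n
  }
  counts
}

#' Multinomial bottleneck sampling
#'
#' Models a technical sampling event (pipetting a subvolume, loading a
#' sequencing chip) as one multinomial draw of `size` items over the current
#' tag frequencies: every cell has the same chance of ending up in the sample.
#'
#' @param x Source composition: a data frame with `tag`/`count` columns or a
#'   (possibly named) non-negative numeric vector; must have a positive total.
#' @param size Number of cells (or reads) sampled, >= 1.
#' @param seed Optional integer seed.
#' @return Sampled counts in the same shape as the input (tibble in, tibble
#'   out), summing exactly to `size`.
#' @export
multinomial_bottleneck <- function(x, size, seed = NULL) {
  check_positive(size, "size")
  if (!is.null(seed)) set.seed(seed)
  counts <- if (is.data.frame(x)) x$count else as.numeric(x)
  if (sum(counts) <= 0) stop("cannot sample from an empty population.", call. = FALSE)
  drawn <- as.numeric(stats::rmultinom(1, size = size, prob = counts))
  if (is.data.frame(x)) {
    out <- tibble::as_tibble(x)
    out$count <- drawn
    out
  } else {
    stats::setNames(drawn, names(x))
  }
}
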
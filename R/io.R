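#' Read and write tag count tables
#'
#' Tag count tables are delimited text (TSV by default, CSV by `.csv`
#' extension) with columns `tag` and `count`; optional extra columns
#' (`replicate`, `time_min`) pass through, so one file can hold replicate
#' reference samples or several timepoints.
#'
#' @param path File path.
#' @param x A data frame with at least `tag` and `count` columns.
#' @return `read_tag_counts()`: a tibble. `write_tag_counts()`: `path`,
#'   invisibly.
#' @export
read_tag_counts <- function(path) {
  out <- read_delim_auto(path)
  if (!all(c("tag", "count") %in% names(out))) {
    stop(path, " must have `tag` and `count` columns.", call. = FALSE)
  }
  out$tag <- as.character(out$tag)
  out
}

#' @rdname read_tag_counts
#' @export
write_tag_counts <- function(x, path) {
  if (!all(c("tag", "count") %in% names(x))) {
    stop("`x` must have `tag` and `count` columns.", call. = FALSE)
  }
  write_delim_auto(x, path)
}

#' Read and write CFU time series
#'
#' Delimited text with columns `time_min` and `cfu_per_ml`; an optional
#' `replicate` column marks replicate platings.
#'
#' @param path File path.
#' @param x A data frame with `time_min` and `cfu_per_ml` columns.
#' @return `read_cfu_series()`: a tibble. `write_cfu_series()`: `path`,
#'   invisibly.
#' @export
read_cfu_series <- function(path) {
  out <- read_delim_auto(path)
  if (!all(c("time_min", "cfu_per_ml") %in% names(out))) {
    stop(path, " must have `time_min` and `cfu_per_ml` columns.", call. = FALSE)
  }
  out
}

#' @rdname read_cfu_series
#' @export
write_cfu_series <- function(x, path) {
  if (!all(c("time_min", "cfu_per_ml") %in% names(x))) {
    stop("`x` must have `time_min` and `cfu_per_ml` columns.", call. = FALSE)
  }
  write_delim_auto(x, path)
}

#' Read and write a bottleneck ledger as YAML
#'
#' The on-disk form lists the ordered sample sizes per side, e.g.
#' ```yaml
#' inoculum:
#' - 1.0e6
#' - 1.0e6
#' sample:
#' - [7.5e4, 9.7e4]   # replicate size measurements of one stage
#' - 1.0e6
#' ```
#'
#' @param path File path.
#' @param ledger A [bottleneck_ledger()], or the raw `inoculum`/`sample` size
#'   lists to write.
#' @return `read_ledger()`: a `bottleneck_ledger`. `write_ledger()`: `path`,
#'   invisibly.
#' @export
read_ledger <- function(path) {
  spec <- yaml::read_yaml(path)
  bottleneck_ledger(inoculum = spec$inoculum, sample = spec$sample)
}

#' @rdname read_ledger
#' @export
write_ledger <- function(ledger, path) {
  if (inherits(ledger, "bottleneck_ledger")) {
    # the ledger stores mean inverses; round-trip through sizes of 1/inverse
    spec <- list(inoculum = as.list(1 / ledger$inoculum_inverse_means),
                 sample = as.list(1 / ledger$sample_inverse_means))
  } else {
    spec <- ledger
  }
  yaml::write_yaml(spec, path)
  invisible(path)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv(path, show_col_types = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE)
  }
}

write_delim_auto <- function(x, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(x, path)
  } else {
    readr::write_tsv(x, path)
  }
  invisible(path)
}

#' Write a synthetic experiment bundle to disk
#'
#' Writes `reference.tsv`, `timepoints.tsv`, `cfu.tsv`, `ledger.yaml` and a
#' JSON ground-truth manifest under `dir`, in exactly the formats
#' [estimate_experiment()] and the command-line interface consume.
#'
#' @param x A `synthetic_experiment` from [generate_experiment_tables()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment_tables <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tag_counts(x$reference, file.path(dir, "reference.tsv"))
  write_tag_counts(x$timepoints, file.path(dir, "timepoints.tsv"))
  write_cfu_series(x$cfu, file.path(dir, "cfu.tsv"))
  write_ledger(x$ledger, file.path(dir, "ledger.yaml"))
  jsonlite::write_json(
    list(beta = x$truth$beta, delta = x$truth$delta, n0 = x$truth$n0,
         theory_nb = as.list(x$truth$theory_nb)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# machine-readable provenance record accompanying every CLI run
write_provenance <- function(path, subcommand, inputs, seed = NULL) {
  jsonlite::write_json(
    list(tool = "tagrates",
         version = as.character(utils::packageVersion("tagrates")),
         subcommand = subcommand,
         inputs = inputs,
         seed = seed,
         r_version = R.version.string,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}
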
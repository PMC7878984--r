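#' Read layout of a barcoded amplicon
#'
#' Geometry of a barcode read: a random region of `random_len` bp (the tag
#' proper, default 30) followed by a fixed strain barcode of `strain_len` bp
#' (default 21) used to verify that genuine tag constructs, not random DNA
#' snippets, were sequenced.
#'
#' @param strain_seq Fixed strain barcode sequence (A/C/G/T).
#' @param random_len Length of the random barcode region (bp).
#' @param strain_len Length of the strain barcode (bp); defaults to
#'   `nchar(strain_seq)`.
#' @return An object of class `read_layout`.
#' @export
read_layout <- function(strain_seq, random_len = 30, strain_len = nchar(strain_seq)) {
  check_positive(random_len, "random_len")
  check_positive(strain_len, "strain_len")
  strain_seq <- toupper(strain_seq)
  if (nchar(strain_seq) != strain_len) {
    stop("`strain_seq` must be exactly `strain_len` bases long.", call. = FALSE)
  }
  if (grepl("[^ACGT]", strain_seq)) stop("`strain_seq` may only contain A/C/G/T.", call. = FALSE)
  structure(list(random_len = as.integer(random_len),
                 strain_len = as.integer(strain_len),
                 strain_seq = strain_seq),
            class = "read_layout")
}

#' @export
print.read_layout <- function(x, ...) {
  cat("<read_layout>", x$random_len, "bp random +", x$strain_len,
      "bp strain barcode", x$strain_seq, "\n")
  invisible(x)
}

#' Read a FASTQ file of barcode reads
#'
#' Thin wrapper over `Biostrings::readDNAStringSet(format = "fastq")`
#' returning plain read sequences; the error model is quality-blind, so
#' qualities are dropped.
#'
#' @param path Path to a FASTQ file (optionally gzipped).
#' @return Character vector of read sequences.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path, call. = FALSE)
  reads <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) stop("malformed FASTQ in ", path, ": ", conditionMessage(e),
                             call. = FALSE)
  )
  as.character(reads)
}

#' Write reads as FASTQ
#'
#' @param reads Character vector of read sequences.
#' @param path Output path (`.gz` suffix compresses).
#' @param ids Optional read identifiers (default `read1`, `read2`, ...).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, ids = NULL) {
  ids <- ids %||% paste0("read", seq_along(reads))
  dss <- Biostrings::DNAStringSet(reads)
  names(dss) <- ids
  # the pipeline ignores qualities, so a constant dummy quality is written
  quals <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  Biostrings::writeXStringSet(dss, path, format = "fastq", qualities = quals,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Filter reads on the strain barcode
#'
#' Keeps reads whose strain-barcode region matches the expected fixed sequence
#' exactly; the pass rate carries the per-base error information used by
#' [estimate_error_rate()]. Reads shorter than the layout are an error.
#'
#' @param reads Character vector of read sequences (see [read_fastq()]).
#' @param layout A [read_layout()].
#' @return A list of class `strain_filter`: `barcodes` (random regions of the
#'   passing reads), `pass` (logical per read), `n_reads`, `n_pass`.
#' @export
filter_strain_barcode <- function(reads, layout) {
  stopifnot(inherits(layout, "read_layout"))
  min_len <- layout$random_len + layout$strain_len
  short <- nchar(reads) < min_len
  if (any(short)) {
    stop("read(s) shorter than the layout (first offender: record ",
         which(short)[1], ").", call. = FALSE)
  }
  strain <- substr(reads, layout$random_len + 1L, min_len)
  pass <- strain == layout$strain_seq
  structure(
    list(barcodes = substr(reads[pass], 1L, layout$random_len),
         pass = pass, n_reads = length(reads), n_pass = sum(pass)),
    class = "strain_filter"
  )
}

#' @export
print.strain_filter <- function(x, ...) {
  cat("<strain_filter>", x$n_pass, "of", x$n_reads, "reads pass (",
      format(100 * x$n_pass / max(x$n_reads, 1), digits = 4), "% )\n")
  invisible(x)
}

#' Per-base error rate from the strain-barcode pass rate
#'
#' With position-independent per-base errors, a fraction `p^strain_len` of
#' reads matches the strain barcode exactly, so the per-base correct-call
#' probability is recovered as `p = (n_pass / n_reads)^(1 / strain_len)`.
#'
#' @param n_reads Total reads.
#' @param n_pass Reads passing the strain filter (> 0).
#' @param strain_len Strain-barcode length (bp).
#' @return `p`, the per-base correct-call probability.
#' @export
estimate_error_rate <- function(n_reads, n_pass, strain_len) {
  check_positive(n_reads, "n_reads")
  check_positive(strain_len, "strain_len")
  if (n_pass <= 0) stop("no reads passed the strain filter; cannot estimate the error rate.",
                        call. = FALSE)
  if (n_pass > n_reads) stop("`n_pass` cannot exceed `n_reads`.", call. = FALSE)
  (n_pass / n_reads)^(1 / strain_len)
}

#' Expected mismatch-class sizes of error reads
#'
#' Under the position-independent substitution model the number of
#' mismatches `m` a read accumulates in its random-barcode region is binomial,
#' `P(m) = C(N_R, m) q^m (1-q)^(N_R - m)` with `q = 1 - p`. Multiplying by the
#' number of filtered reads gives the expected count of reads in each mismatch
#' class; classes expected to contain at least one read (up to `m_max`) set
#' the budget for how many extraneous sequences may legitimately be explained
#' by sequencing error.
#'
#' @param p Per-base correct-call probability (from [estimate_error_rate()]).
#' @param n_pass Number of reads after strain filtering.
#' @param random_len Random-barcode length (bp).
#' @return A tibble of class `mismatch_budget` with columns `m`, `prob`,
#'   `expected`, and attributes `m_max`, `p`, `q`, `n_pass`, `random_len`.
#' @export
mismatch_budget <- function(p, n_pass, random_len = 30) {
  check_number(p, "p", lower = 0, upper = 1)
  if (p <= 0) stop("`p` must be > 0.", call. = FALSE)
  check_positive(n_pass, "n_pass")
  q <- 1 - p
  m <- 0:random_len
  prob <- stats::dbinom(m, random_len, q)
  expected <- n_pass * prob
  out <- new_tbl(m = m, prob = prob, expected = expected)
  attr(out, "m_max") <- if (any(expected >= 1)) max(m[expected >= 1]) else 0L
  attr(out, "p") <- p
  attr(out, "q") <- q
  attr(out, "n_pass") <- n_pass
  attr(out, "random_len") <- random_len
  class(out) <- c("mismatch_budget", class(out))
  out
}

# Hamming distance from each query string to its nearest target string;
# all strings must share one length. Returns a tibble (distance, nearest).
# Ties resolve to the lexicographically smallest target.
nearest_hamming <- function(queries, targets) {
  if (length(queries) == 0L) {
    return(new_tbl(distance = integer(0), nearest = character(0)))
  }
  len <- unique(nchar(c(queries, targets)))
  if (length(len) != 1L) stop("sequences must share one length.", call. = FALSE)
  ord <- order(targets)
  targets <- targets[ord]
  enc <- function(x) {
    m <- matrix(utf8ToInt(paste(x, collapse = "")), nrow = length(x),
                ncol = len, byrow = TRUE)
    m
  }
  tm <- enc(targets)
  bases <- unique(as.vector(tm))
  # chunk the queries so the distance matrix stays small
  idx_chunks <- ceiling(seq_along(queries) / 2000)
  chunks <- split(queries, factor(idx_chunks, levels = unique(idx_chunks)))
  out <- purrr::map_dfr(chunks, function(qs) {
    qm <- enc(qs)
    matches <- matrix(0, nrow = length(qs), ncol = length(targets))
    for (b in bases) {
      matches <- matches + (qm == b) %*% t(tm == b)
    }
    dist <- len - matches
    idx <- apply(dist, 1L, which.min)
    new_tbl(distance = as.integer(dist[cbind(seq_along(qs), idx)]),
            nearest = targets[idx])
  })
  out
}

#' Remove spurious sequences from clustered barcode counts
#'
#' After exact-identity clustering, more distinct sequences than the `k`
#' constructed barcodes remain; the surplus mixes genuine reads carrying
#' sequencing errors with spurious sequences (PCR artefacts, contamination).
#' The sequences are sorted by abundance; the top `k` are designated true
#' barcodes. Every extraneous sequence is assigned the mismatch class `m` of
#' its Hamming distance to the nearest true barcode. Classes with fewer than
#' one expected error read (`m > m_max`) are discarded outright; within each
#' class `m <= m_max`, only the `round(expected_m)` most abundant extraneous
#' sequences are kept as error reads and, by default, merged back into their
#' nearest parent barcode's count.
#'
#' @param counts A data frame with columns `sequence` and `count` from exact
#'   clustering (see [cluster_reads()]).
#' @param k Expected number of true barcodes.
#' @param budget A [mismatch_budget()].
#' @param merge If `TRUE` (default) retained error reads are added to their
#'   parent barcode's count; `FALSE` keeps them separate for diagnostics.
#' @return A list of class `despurify_result`: `table` (tibble `tag`,
#'   `count` of the true barcodes, abundance-sorted), `retained` (error
#'   sequences kept, with `m` and `parent`), `discarded` (spurious), and
#'   bookkeeping counters (`n_merged`, `n_discarded`).
#' @export
despurify <- function(counts, k, budget, merge = TRUE) {
  stopifnot(inherits(budget, "mismatch_budget"))
  counts <- tibble::as_tibble(counts)
  if (!all(c("sequence", "count") %in% names(counts))) {
    stop("`counts` must have `sequence` and `count` columns.", call. = FALSE)
  }
  counts <- dplyr::arrange(counts, dplyr::desc(.data$count), .data$sequence)
  if (nrow(counts) < k) {
    warning("fewer distinct sequences (", nrow(counts), ") than expected barcodes (",
            k, "); treating all as true barcodes.")
    k <- nrow(counts)
  }
  true <- counts[seq_len(k), ]
  extras <- counts[-seq_len(k), , drop = FALSE]
  m_max <- attr(budget, "m_max")

  if (nrow(extras) == 0L) {
    retained <- new_tbl(sequence = character(0), count = numeric(0),
                        m = integer(0), parent = character(0))
    discarded <- retained
  } else {
    nh <- nearest_hamming(extras$sequence, true$sequence)
    extras$m <- nh$distance
    extras$parent <- nh$nearest
    keep <- logical(nrow(extras))
    for (mm in unique(extras$m)) {
      if (mm > m_max) next
      cap <- round(budget$expected[budget$m == mm])
      in_class <- which(extras$m == mm) # already abundance-sorted
      keep[utils::head(in_class, cap)] <- TRUE
    }
    retained <- extras[keep, ]
    discarded <- extras[!keep, ]
  }

  table <- new_tbl(tag = true$sequence, count = true$count)
  if (merge && nrow(retained) > 0L) {
    add <- dplyr::summarise(dplyr::group_by(retained, .data$parent),
                            extra = sum(.data$count), .groups = "drop")
    idx <- match(add$parent, table$tag)
    table$count[idx] <- table$count[idx] + add$extra
  }
  table <- dplyr::arrange(table, dplyr::desc(.data$count), .data$tag)

  structure(
    list(table = table, retained = retained, discarded = discarded,
         n_merged = if (merge) sum(retained$count) else 0,
         n_discarded = sum(discarded$count), merged = merge),
    class = "despurify_result"
  )
}

#' @export
print.despurify_result <- function(x, ...) {
  cat("<despurify_result>", nrow(x$table), "true barcodes;",
      nrow(x$retained), "error sequences retained (", x$n_merged, "reads",
      if (x$merged) "merged" else "kept separate", ");",
      nrow(x$discarded), "spurious sequences discarded (", x$n_discarded, "reads )\n")
  invisible(x)
}

#' Exact-identity clustering of barcode sequences
#'
#' @param barcodes Character vector of random-barcode sequences.
#' @return A tibble with columns `sequence` and `count`, sorted by abundance
#'   (ties lexicographic).
#' @export
cluster_reads <- function(barcodes) {
  out <- dplyr::count(new_tbl(sequence = barcodes), .data$sequence,
                      name = "count")
  dplyr::arrange(out, dplyr::desc(.data$count), .data$sequence)
}

#' Barcode counting pipeline: reads to tag count table
#'
#' Full processing chain: strain-barcode filtering, per-base error-rate
#' estimation, expected mismatch-class budgeting, exact clustering, and
#' abundance-ranked spurious-read removal with error-read merging.
#'
#' @param reads Character vector of read sequences (see [read_fastq()]) or a
#'   `strain_filter` result.
#' @param layout A [read_layout()].
#' @param k Expected number of true barcodes.
#' @param merge Merge retained error reads into their parents (default TRUE).
#' @return A tibble of class `tag_count_table` with columns `tag`, `count`
#'   (abundance-sorted) and a `provenance` attribute recording `n_reads`,
#'   `n_pass`, `p`, `m_max`, `n_merged`, `n_discarded`.
#' @export
count_tags <- function(reads, layout, k, merge = TRUE) {
  filt <- if (inherits(reads, "strain_filter")) reads else filter_strain_barcode(reads, layout)
  p <- estimate_error_rate(filt$n_reads, filt$n_pass, layout$strain_len)
  budget <- mismatch_budget(p, filt$n_pass, layout$random_len)
  clustered <- cluster_reads(filt$barcodes)
  ds <- despurify(clustered, k = k, budget = budget, merge = merge)
  out <- ds$table
  attr(out, "provenance") <- list(
    n_reads = filt$n_reads, n_pass = filt$n_pass, p = p,
    m_max = attr(budget, "m_max"),
    n_merged = ds$n_merged, n_discarded = ds$n_discarded
  )
  attr(out, "despurify") <- ds
  class(out) <- c("tag_count_table", class(out))
  out
}
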
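#' Generate a random barcode library
#'
#' Draws `k` distinct random barcodes of `random_len` bp with a minimum
#' pairwise Hamming distance, so that sequencing-error classes up to the
#' mismatch budget cannot collide between barcodes. Random 30-mers are on
#' average ~22 mismatches apart, so the default floor of 5 is essentially
#' always satisfiable for realistic `k`.
#'
#' @param k Number of barcodes.
#' @param random_len Barcode length (bp).
#' @param min_dist Minimum pairwise Hamming distance (default 5).
#' @param seed Optional integer seed.
#' @param max_tries Redraw attempts before giving up.
#' @return A tibble with columns `tag` (id) and `sequence`.
#' @export
generate_barcode_library <- function(k, random_len = 30, min_dist = 5,
                                     seed = NULL, max_tries = 50) {
  check_positive(k, "k")
  check_positive(random_len, "random_len")
  if (4^min(random_len, 30) < 10 * k) {
    stop("sequence space too small for ", k, " barcodes of length ", random_len, ".",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  draw <- function(n) {
    m <- matrix(sample(c("A", "C", "G", "T"), n * random_len, replace = TRUE),
                nrow = n)
    apply(m, 1L, paste, collapse = "")
  }
  seqs <- character(0)
  tries <- 0
  while (length(seqs) < k) {
    tries <- tries + 1
    if (tries > max_tries) {
      stop("could not satisfy the distance floor of ", min_dist,
           " after ", max_tries, " attempts.", call. = FALSE)
    }
    cand <- unique(draw(k - length(seqs)))
    if (length(seqs) > 0) {
      nh <- nearest_hamming(cand, seqs)
      cand <- cand[nh$distance >= min_dist]
    }
    # enforce the floor within the candidate batch itself
    for (s in cand) {
      if (length(seqs) == 0 || min(nearest_hamming(s, seqs)$distance) >= min_dist) {
        seqs <- c(seqs, s)
        if (length(seqs) == k) break
      }
    }
  }
  new_tbl(tag = sprintf("bc%0*d", nchar(as.character(k)), seq_len(k)),
          sequence = seqs)
}

#' Generate synthetic barcode reads with controlled errors
#'
#' Simulates a sequencing run over a barcode library: each read is a source
#' barcode followed by the strain barcode, with independent per-base
#' substitutions at rate `q` to a uniformly chosen other base (no indels, no
#' quality structure -- matching the substitution-only error model the
#' counting pipeline assumes). Optionally plants contaminant reads whose
#' random region is unrelated to every library barcode but whose strain
#' barcode is intact, emulating foreign amplicons that survive filtering.
#' Ground truth records the error-free source of every read.
#'
#' @param library A tibble from [generate_barcode_library()].
#' @param layout A [read_layout()]; `random_len` must match the library.
#' @param depth Number of reads to generate.
#' @param q Per-base substitution probability in `[0, 0.5)`.
#' @param weights Per-barcode abundance weights (default uniform).
#' @param n_contaminants Number of contaminant reads to plant.
#' @param seed Optional integer seed.
#' @return A list of class `synthetic_reads`: `reads` (character vector, in
#'   randomized order), `truth` (tibble: `read`, `source` tag id or
#'   `"contaminant"`), `library`, `layout`, `q`.
#' @export
generate_reads <- function(library, layout, depth, q = 0.01, weights = NULL,
                           n_contaminants = 0, seed = NULL) {
  stopifnot(inherits(layout, "read_layout"))
  check_positive(depth, "depth")
  check_number(q, "q", lower = 0, upper = 0.5)
  if (unique(nchar(library$sequence)) != layout$random_len) {
    stop("library barcode length does not match `layout$random_len`.", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(library)
  weights <- weights %||% rep(1, k)

  src <- sample.int(k, depth, replace = TRUE, prob = weights)
  bases <- c("A", "C", "G", "T")
  read_len <- layout$random_len + layout$strain_len

  # integer-coded template matrix, one row per read
  lib_mat <- matrix(match(unlist(strsplit(paste0(library$sequence, layout$strain_seq), "")),
                          bases),
                    nrow = k, ncol = read_len, byrow = TRUE)
  reads_mat <- lib_mat[src, , drop = FALSE]
  sources <- library$tag[src]

  if (n_contaminants > 0) {
    cont <- matrix(sample.int(4, n_contaminants * layout$random_len, replace = TRUE),
                   nrow = n_contaminants)
    strain_codes <- match(strsplit(layout$strain_seq, "")[[1]], bases)
    cont <- cbind(cont, matrix(strain_codes, nrow = n_contaminants,
                               ncol = layout$strain_len, byrow = TRUE))
    reads_mat <- rbind(reads_mat, cont)
    sources <- c(sources, rep("contaminant", n_contaminants))
  }

  n_total <- nrow(reads_mat)
  err <- which(stats::runif(n_total * read_len) < q)
  if (length(err) > 0) {
    # substitute with one of the three other bases, uniformly
    shift <- sample.int(3, length(err), replace = TRUE)
    reads_mat[err] <- (reads_mat[err] - 1L + shift) %% 4L + 1L
  }

  char_mat <- matrix(bases[reads_mat], nrow = n_total)
  reads <- do.call(paste0, as.data.frame(char_mat, stringsAsFactors = FALSE))

  ord <- sample.int(n_total)
  structure(
    list(reads = reads[ord],
         truth = new_tbl(read = reads[ord], source = sources[ord]),
         library = library, layout = layout, q = q),
    class = "synthetic_reads"
  )
}

#' @export
print.synthetic_reads <- function(x, ...) {
  cat("<synthetic_reads>", length(x$reads), "reads over", nrow(x$library),
      "barcodes, q =", x$q, "\n")
  invisible(x)
}

#' Generate a complete synthetic tag-count experiment
#'
#' One call produces everything the estimation pipeline consumes, with known
#' ground truth: a geometric tag library, a tau-leaping birth-death
#' trajectory recorded at the requested timepoints, replicate reference
#' (time-0) count tables and per-timepoint count tables each pushed through
#' the configured technical bottleneck chains, a CFU series taken from the
#' simulated census, and the matching [bottleneck_ledger()].
#'
#' @param beta,delta True division and death rates (1/min).
#' @param times Timepoints (min) at which count tables are produced; time 0
#'   is always included for the CFU series.
#' @param k,prob Library size and geometric probability parameter.
#' @param dt Tau-leap step (min).
#' @param inoculum_sizes,sample_sizes Technical bottleneck chains applied to
#'   the reference and timepoint samples.
#' @param n_reference Number of replicate reference samples.
#' @param seed Optional integer seed.
#' @param dir If non-`NULL`, the tables are also written there as TSV/YAML
#'   (see [read_tag_counts()], [read_cfu_series()], [read_ledger()]) together
#'   with a JSON ground-truth manifest.
#' @return A list of class `synthetic_experiment`: `reference` (tibble `tag`,
#'   `count`, `replicate`), `timepoints` (tibble `tag`, `count`, `time_min`),
#'   `cfu` (tibble `time_min`, `cfu_per_ml`), `ledger`, `truth` (list with
#'   `beta`, `delta`, `n0`, `theory_nb` per timepoint).
#' @export
generate_experiment_tables <- function(beta, delta, times, k = 1000, prob = 1 / 1000,
                                       dt = 0.01,
                                       inoculum_sizes = c(1e6, 1e6),
                                       sample_sizes = c(1e5, 1e6),
                                       n_reference = 3, seed = NULL, dir = NULL) {
  if (!is.null(seed)) set.seed(seed)
  times <- sort(unique(times[times > 0]))
  init <- geometric_library(k, prob)
  n0 <- sum(init$count)

  sim <- simulate_bd(init, beta = beta, delta = delta, t = max(times), dt = dt,
                     n_reps = 1, record_times = times, record_counts = TRUE)

  chain <- function(counts, sizes) {
    for (size in sizes) counts <- as.numeric(stats::rmultinom(1, size, prob = counts))
    counts
  }

  reference <- purrr::map_dfr(seq_len(n_reference), function(repl) {
    new_tbl(tag = init$tag, count = chain(init$count, inoculum_sizes),
            replicate = repl)
  })

  rec_idx <- match(times, sim$record_times)
  timepoints <- purrr::map_dfr(seq_along(times), function(i) {
    counts <- sim$counts[[rec_idx[i]]][, 1]
    new_tbl(tag = init$tag, count = chain(counts, sample_sizes),
            time_min = times[i])
  })

  census <- dplyr::filter(sim$census, .data$rep == 1)
  cfu <- new_tbl(time_min = census$time, cfu_per_ml = census$census)
  cfu <- dplyr::filter(cfu, .data$time_min %in% c(0, times))

  ledger <- bottleneck_ledger(inoculum = as.list(inoculum_sizes),
                              sample = as.list(sample_sizes))
  theory_nb <- if (beta + delta > 0) {
    stats::setNames(founder_theory(beta, delta, t = times, n0 = n0),
                    paste0("t", times))
  } else {
    stats::setNames(rep(NA_real_, length(times)), paste0("t", times))
  }
  truth <- list(beta = beta, delta = delta, n0 = n0, theory_nb = theory_nb)

  out <- structure(
    list(reference = reference, timepoints = timepoints, cfu = cfu,
         ledger = ledger, init = init, truth = truth),
    class = "synthetic_experiment"
  )
  if (!is.null(dir)) write_experiment_tables(out, dir)
  out
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat("<synthetic_experiment> beta =", x$truth$beta, "delta =", x$truth$delta,
      "n0 =", x$truth$n0, ";", length(unique(x$timepoints$time_min)),
      "timepoints,", length(unique(x$reference$replicate)), "reference replicates\n")
  invisible(x)
}
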
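test_that("read layout validation", {
  layout <- read_layout("ACGTACGTACGTACGTACGTA")
  expect_equal(layout$strain_len, 21L)
  expect_equal(layout$random_len, 30L)
  expect_error(read_layout("ACGT", strain_len = 21), "exactly")
  expect_error(read_layout("ACGTN"), "A/C/G/T")
})

test_that("strain filtering keeps exact matches only", {
  layout <- read_layout("ACGTACGTACGTACGTACGTA")
  rs <- make_read_set(k = 10, depth = 500, q = 0, seed = 11)
  filt <- filter_strain_barcode(rs$reads$reads, rs$layout)
  expect_equal(filt$n_pass, 500) # error-free reads all pass

  wrong <- read_layout(strrep("T", 21))
  expect_equal(filter_strain_barcode(rs$reads$reads, wrong)$n_pass, 0)

  expect_error(filter_strain_barcode(c(rs$reads$reads, "ACGT"), rs$layout),
               "shorter than the layout")
})

test_that("filter pass rate reflects the per-base error rate", {
  rs <- make_read_set(k = 10, depth = 2e4, q = 0.01, seed = 12)
  filt <- filter_strain_barcode(rs$reads$reads, rs$layout)
  expected <- 0.99^21
  se <- sqrt(expected * (1 - expected) / filt$n_reads)
  expect_lt(abs(filt$n_pass / filt$n_reads - expected), 3 * se)
  # and the error rate is recovered from the pass rate
  p_hat <- estimate_error_rate(filt$n_reads, filt$n_pass, 21)
  expect_equal(p_hat, 0.99, tolerance = 2e-3)
})

test_that("error-rate estimation arithmetic", {
  expect_equal(estimate_error_rate(100, 100, 21), 1)
  expect_equal(estimate_error_rate(1e5, 8.1e4, 21), 0.81^(1 / 21))
  expect_equal(estimate_error_rate(1e5, 8.1e4, 21), 0.99002, tolerance = 1e-5)
  expect_error(estimate_error_rate(100, 0, 21), "cannot estimate")
})

test_that("mismatch budget is binomial and sets m_max where < 1 read is expected", {
  perfect <- mismatch_budget(1, n_pass = 1e5, random_len = 30)
  expect_equal(perfect$prob[1], 1)
  expect_equal(attr(perfect, "m_max"), 0L)

  b <- mismatch_budget(0.99, n_pass = 1e5, random_len = 30)
  expect_equal(sum(b$prob), 1, tolerance = 1e-12)
  expect_equal(b$prob[b$m == 0], 0.7397, tolerance = 1e-4)
  expect_equal(b$prob[b$m == 1], 0.22415, tolerance = 1e-4)
  expect_equal(b$expected[b$m == 2], 3282, tolerance = 1e-3)
  expect_equal(b$expected[b$m == 5], 1.108, tolerance = 1e-2)
  expect_lt(b$expected[b$m == 6], 1)
  expect_equal(attr(b, "m_max"), 5L)
})

test_that("despurify retains budgeted error reads and discards the rest", {
  # two true barcodes, one near error sequence, one distant contaminant
  counts <- tibble::tibble(
    sequence = c("AAAAAAAA", "CCCCCCCC", "AAAAAAAT", "GGGGTTTT"),
    count = c(100, 90, 3, 2)
  )
  budget <- mismatch_budget(0.98, n_pass = 195, random_len = 8)
  expect_gte(budget$expected[budget$m == 1], 1)
  expect_lt(budget$expected[budget$m == 4], 1)

  res <- despurify(counts, k = 2, budget = budget)
  expect_equal(res$table$tag, c("AAAAAAAA", "CCCCCCCC"))
  expect_equal(res$table$count, c(103, 90)) # error reads merged into parent
  expect_equal(res$retained$sequence, "AAAAAAAT")
  expect_equal(res$retained$parent, "AAAAAAAA")
  expect_equal(res$discarded$sequence, "GGGGTTTT")
  expect_equal(res$n_discarded, 2)

  # merge = FALSE keeps the error reads separate for diagnostics
  sep <- despurify(counts, k = 2, budget = budget, merge = FALSE)
  expect_equal(sep$table$count, c(100, 90))
  expect_equal(sep$n_merged, 0)

  # deterministic under input permutation
  perm <- despurify(counts[c(3, 1, 4, 2), ], k = 2, budget = budget)
  expect_equal(perm$table, res$table)
  expect_equal(perm$discarded$sequence, res$discarded$sequence)

  expect_warning(despurify(counts[1:2, ], k = 5, budget = budget), "fewer distinct")
})

test_that("per-class caps limit how many extraneous sequences survive", {
  # budget expecting ~2 single-mismatch reads; plant 4 candidate sequences
  counts <- tibble::tibble(
    sequence = c("AAAAAAAAAA", "CCCCCCCCCC",
                 "AAAAAAAAAT", "AAAAAAAAAG", "TAAAAAAAAA", "AAAAACAAAA"),
    count = c(500, 400, 9, 7, 5, 3)
  )
  budget <- mismatch_budget(1 - 2.16e-4, n_pass = 924, random_len = 10)
  cap <- round(budget$expected[budget$m == 1])
  expect_equal(cap, 2)
  res <- despurify(counts, k = 2, budget = budget)
  # only the `cap` most abundant distance-1 sequences are kept
  expect_equal(res$retained$sequence, c("AAAAAAAAAT", "AAAAAAAAAG"))
  expect_equal(nrow(res$discarded), 2)
})

test_that("error-free pipeline is exactly injective with zero discards", {
  rs <- make_read_set(k = 15, depth = 3000, q = 0, seed = 13)
  tab <- count_tags(rs$reads$reads, rs$layout, k = 15)
  expect_setequal(tab$tag, rs$library$sequence)
  truth_counts <- table(rs$reads$truth$source)
  lib_by_tag <- stats::setNames(rs$library$sequence, rs$library$tag)
  expect_equal(unname(tab$count[match(lib_by_tag[names(truth_counts)], tab$tag)]),
               as.numeric(truth_counts))
  prov <- attr(tab, "provenance")
  expect_equal(prov$n_discarded, 0)
  expect_equal(prov$p, 1)
})

test_that("noisy pipeline conserves reads and assigns them to their sources", {
  rs <- make_read_set(k = 20, depth = 2e4, q = 0.01, n_contaminants = 30, seed = 14)
  tab <- count_tags(rs$reads$reads, rs$layout, k = 20)
  prov <- attr(tab, "provenance")
  ds <- attr(tab, "despurify")

  # bookkeeping identity: retained (merged) + discarded = filtered reads
  expect_equal(sum(tab$count) + prov$n_discarded, prov$n_pass)

  # contaminants that passed the strain filter sit far from every barcode
  filt <- filter_strain_barcode(rs$reads$reads, rs$layout)
  cont_regions <- substr(rs$reads$truth$read[rs$reads$truth$source == "contaminant"], 1, 30)
  cont_in <- intersect(cont_regions, c(ds$retained$sequence, ds$discarded$sequence))
  expect_true(all(cont_in %in% ds$discarded$sequence))

  # read-level assignment accuracy against generator ground truth
  assignment <- c(stats::setNames(tab$tag, tab$tag),
                  stats::setNames(ds$retained$parent, ds$retained$sequence))
  truth <- rs$reads$truth[filt$pass, ]
  truth$region <- substr(truth$read, 1, 30)
  truth$assigned <- assignment[truth$region]
  scored <- truth[!is.na(truth$assigned) & truth$source != "contaminant", ]
  lib_by_tag <- stats::setNames(rs$library$sequence, rs$library$tag)
  accuracy <- mean(scored$assigned == lib_by_tag[scored$source])
  expect_gte(accuracy, 0.99)
})
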
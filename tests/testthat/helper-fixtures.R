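# shared fixture builders; everything is generated in code at test time

# uniform k-tag reference profile
uniform_reference <- function(k) {
  reference_profile(tibble::tibble(tag = sprintf("t%04d", seq_len(k)),
                                   count = rep(1, k)))
}

# founder-size estimate from a single multinomial draw of `size` cells over
# uniform frequencies -- the sampling interpretation of the estimator
draw_founder <- function(size, k) {
  tags <- sprintf("t%04d", seq_len(k))
  ref <- reference_profile(tibble::tibble(tag = tags, count = rep(1, k)))
  draw <- stats::rmultinom(1, size, prob = rep(1 / k, k))[, 1]
  founder_size(tibble::tibble(tag = tags, count = draw), ref)$value
}

# brute-force pairwise Hamming distance oracle (independent of the package's
# vectorized implementation)
pairwise_hamming_oracle <- function(seqs) {
  mats <- strsplit(seqs, "")
  n <- length(seqs)
  d <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(mats[[i]] != mats[[j]])
    }
  }
  d
}

# small synthetic read set shared by the read-pipeline tests
make_read_set <- function(k = 20, depth = 2e4, q = 0.01, n_contaminants = 0,
                          seed = 42) {
  layout <- read_layout("ACGTACGTACGTACGTACGTA") # fixed 21-bp strain barcode
  lib <- generate_barcode_library(k, random_len = 30, seed = seed)
  reads <- generate_reads(lib, layout, depth = depth, q = q,
                          n_contaminants = n_contaminants, seed = seed + 1)
  list(layout = layout, library = lib, reads = reads)
}
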
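test_that("founder size matches the hand-evaluated two-tag case", {
  ref <- reference_profile(tibble::tibble(tag = c("a", "b"), count = c(50, 50)))
  est <- founder_size(tibble::tibble(tag = c("a", "b"), count = c(60, 40)), ref)
  # per-tag terms 0.01/0.25 = 0.04, mean 0.04, N_B = 25
  expect_equal(est$value, 25)
  expect_false(est$corrected)
  expect_false(est$negative_flag)
})

test_that("zero drift gives an infinite, flagged founder size", {
  ref <- reference_profile(tibble::tibble(tag = c("a", "b", "c"), count = c(2, 3, 5)))
  est <- founder_size(tibble::tibble(tag = c("a", "b", "c"), freq = c(0.2, 0.3, 0.5)), ref)
  expect_identical(est$value, Inf)
  expect_true(est$identical_profiles)
})

test_that("profile validation rejects degenerate inputs", {
  ref <- reference_profile(tibble::tibble(tag = c("a", "b"), count = c(1, 1)))
  expect_error(founder_size(tibble::tibble(tag = c("a", "x"), count = c(1, 1)), ref),
               "different tag sets")
  # reference tags at frequency 0 are excluded; dropping below 2 usable tags errors
  ref0 <- reference_profile(tibble::tibble(tag = c("a", "b", "c"), count = c(5, 5, 0)))
  est <- founder_size(tibble::tibble(tag = c("a", "b", "c"), count = c(6, 4, 1)), ref0)
  expect_equal(est$n_excluded, 1L)
  expect_equal(est$excluded_tags, "c")
  ref1 <- reference_profile(tibble::tibble(tag = c("a", "b"), count = c(5, 0)))
  expect_error(founder_size(tibble::tibble(tag = c("a", "b"), count = c(5, 1)), ref1),
               "fewer than 2 usable tags")
  expect_error(tag_profile(tibble::tibble(tag = "a", count = 1)), "at least 2 tags")
  expect_error(tag_profile(tibble::tibble(tag = c("a", "b"), freq = c(0.6, 0.5))),
               "sum to 1")
})

test_that("estimator inverts multinomial sampling: mean 1/N_B equals 1/S", {
  set.seed(101)
  k <- 1000
  for (S in c(1e2, 1e3, 1e4)) {
    inv <- replicate(200, 1 / draw_founder(S, k))
    se <- stats::sd(inv) / sqrt(length(inv))
    expect_lt(abs(mean(inv) - 1 / S), 3 * se)
  }
})

test_that("bottleneck corrections subtract mean inverse sample sizes", {
  ref <- reference_profile(tibble::tibble(tag = c("a", "b"), count = c(50, 50)))
  obs <- tibble::tibble(tag = c("a", "b"), count = c(60, 40))
  raw <- founder_size(obs, ref)
  # empty ledger and infinite sample sizes are both no-ops
  expect_equal(founder_size(obs, ref, bottleneck_ledger())$value, raw$value)
  inf_ledger <- bottleneck_ledger(inoculum = c(Inf, Inf), sample = c(Inf))
  expect_equal(founder_size(obs, ref, inf_ledger)$value, raw$value)

  led <- bottleneck_ledger(sample = c(1e5, 1e6), inoculum = c(1e6, 1e6))
  corr <- founder_size(obs, ref, led)
  expect_equal(corr$value, 1 / (1 / raw$value - 1.3e-5))
  expect_true(corr$corrected)

  # replicate sizes enter as the mean of inverses, not the inverse of the mean
  led2 <- bottleneck_ledger(sample = list(c(100, 400)))
  corr2 <- founder_size(obs, ref, led2)
  expect_equal(corr2$value, 1 / (1 / raw$value - mean(c(1 / 100, 1 / 400))))

  # harmonic-sum arithmetic at the scales of the validation study
  expect_equal(1 / (1 / 3.027e4 - 1.3e-5), 4.991e4, tolerance = 1e-3)
})

test_that("over-correction is flagged, not clipped", {
  ref <- reference_profile(tibble::tibble(tag = c("a", "b"), count = c(50, 50)))
  obs <- tibble::tibble(tag = c("a", "b"), count = c(51, 49))
  led <- bottleneck_ledger(sample = 10) # 1/10 far exceeds the drift
  est <- founder_size(obs, ref, led)
  expect_true(est$negative_flag)
  expect_lt(est$value, 0)
  expect_error(rate_estimates(r = 0.01, n0 = 1e5, nt = 2e5, nb = est),
               "negative-flagged")
})

test_that("closed-form mean founder size matches the validation parameter sets", {
  expect_equal(founder_theory(beta = 0.01, delta = 0.03, t = 120, n0 = 1e6),
               4.99e4, tolerance = 0.005)
  expect_equal(founder_theory(beta = 0.03, delta = 0.01, t = 120, n0 = 1e6),
               5.50e5, tolerance = 0.005)
  # balanced-rates limit N0 / ((beta + delta) t), continuous across r = 0
  expect_equal(founder_theory(0.02, 0.02, t = 100, n0 = 1e6), 2.5e5)
  eps <- 1e-6
  expect_equal(founder_theory(0.02 + eps, 0.02, 100, 1e6) / 2.5e5, 1, tolerance = 1e-4)
  expect_equal(founder_theory(0.02, 0.02 + eps, 100, 1e6) / 2.5e5, 1, tolerance = 1e-4)
  expect_error(founder_theory(0.01, 0.03, t = 0, n0 = 1e6), "t")
})

test_that("birth-death frequency variance evaluates and reduces correctly", {
  expect_equal(bd_freq_variance(0.01, 0.03, t = 0, n0 = 1e6, f0 = 0.3), 0)
  expect_equal(bd_freq_variance(0.01, 0.03, t = 120, n0 = 1e6, f0 = 0.001),
               2.003e-8, tolerance = 1e-3)
  # pure death reduces to the binomial-survival form (exp(dt) - 1)/N0 f(1-f)
  d <- 0.05; tt <- 30; n0 <- 1e4; f0 <- 0.2
  expect_equal(bd_freq_variance(0, d, tt, n0, f0),
               (exp(d * tt) - 1) / n0 * f0 * (1 - f0))
})

test_that("volume rescaling multiplies and composes", {
  ref <- reference_profile(tibble::tibble(tag = c("a", "b"), count = c(50, 50)))
  est <- founder_size(tibble::tibble(tag = c("a", "b"), count = c(60, 40)), ref)
  up <- scale_volume(est, measured_volume = 200, reference_volume = 1000)
  expect_equal(up$value, est$value * 5)
  expect_equal(up$volume_scale, 5)
  expect_equal(scale_volume(est, 3, 3)$value, est$value)
  ab <- scale_volume(scale_volume(est, 1, 4), 4, 10)
  ac <- scale_volume(est, 1, 10)
  expect_equal(ab$value, ac$value)
  expect_equal(ab$volume_scale, ac$volume_scale)
})

test_that("death-emulation scaling applies 1/(1 - exp(-delta t))", {
  ref <- reference_profile(tibble::tibble(tag = c("a", "b"), count = c(50, 50)))
  est <- founder_size(tibble::tibble(tag = c("a", "b"), count = c(60, 40)), ref)
  est$value <- 1000; est$raw_value <- 1000
  scaled <- scale_death_emulation(est, delta = 0.1, t = 20)
  expect_equal(scaled$value, 1000 / (1 - exp(-2)), tolerance = 1e-12)
  expect_equal(scaled$emulation_scale, 1.1565, tolerance = 1e-4)
  expect_error(scale_death_emulation(est, delta = 0, t = 20), "diverges")
  # factor tends to 1 as delta t grows
  expect_equal(scale_death_emulation(est, 1, 1e3)$value, 1000)
})

test_that("reference profiles average replicate frequencies", {
  ref <- reference_profile(tibble::tibble(
    tag = rep(c("a", "b"), 2),
    count = c(60, 40, 40, 60),
    replicate = rep(1:2, each = 2)
  ))
  expect_equal(ref$mean_freq, c(0.5, 0.5))
  expect_equal(attr(ref, "n_replicates"), 2L)
})
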
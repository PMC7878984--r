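test_that("geometric libraries have the stated support and moments", {
  lib <- geometric_library(1000, 1 / 1000, seed = 7)
  expect_equal(nrow(lib), 1000)
  expect_true(all(lib$count >= 1)) # every constructed clone exists
  # census close to k / prob = 1e6
  expect_equal(sum(lib$count) / 1e6, 1, tolerance = 0.1)
  # degenerate parameter: every tag a single cell
  one <- geometric_library(50, 1 - 1e-12, seed = 1)
  expect_true(all(one$count == 1))
  # empirical mean matches 1/prob
  set.seed(3)
  draws <- stats::rgeom(1e4, 0.01) + 1
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 100), 3 * se)
})

test_that("tau-leap trajectories are constant without events and reproducible", {
  lib <- geometric_library(20, 1 / 20, seed = 5)
  still <- simulate_bd(lib, beta = 0, delta = 0, t = 10, dt = 0.1, n_reps = 3, seed = 1)
  expect_true(all(still$final_counts == matrix(lib$count, 20, 3)))

  a <- simulate_bd(lib, 0.02, 0.01, t = 20, dt = 0.05, n_reps = 4, seed = 99)
  b <- simulate_bd(lib, 0.02, 0.01, t = 20, dt = 0.05, n_reps = 4, seed = 99)
  expect_identical(a$final_counts, b$final_counts)
  expect_identical(a$census, b$census)
})

test_that("tau-leap ensemble mean census follows exponential decay", {
  lib <- geometric_library(100, 1 / 100, seed = 21)
  n0 <- sum(lib$count)
  sim <- simulate_bd(lib, beta = 0.01, delta = 0.03, t = 30, dt = 0.01,
                     n_reps = 100, seed = 22)
  fin <- colSums(sim$final_counts)
  se <- stats::sd(fin) / sqrt(length(fin))
  expect_lt(abs(mean(fin) - n0 * exp(-0.02 * 30)), 3 * se)
})

test_that("tau-leap per-tag variance matches the closed form and exact simulation", {
  beta <- 0.01; delta <- 0.03; tt <- 20
  init <- tibble::tibble(tag = sprintf("t%02d", 1:10), count = rep(50, 10))
  sim <- simulate_bd(init, beta, delta, t = tt, dt = 0.01, n_reps = 400, seed = 31)
  r <- beta - delta
  var_theory <- 50 * (beta + delta) / r * exp(r * tt) * (exp(r * tt) - 1)
  obs_var <- mean(apply(sim$final_counts, 1, stats::var))
  # sampling error of a variance estimate ~ sigma^2 sqrt(2/(n-1))
  tol <- 3 * var_theory * sqrt(2 / 399)
  expect_lt(abs(obs_var - var_theory), tol)
  obs_mean <- mean(sim$final_counts)
  expect_equal(obs_mean / (50 * exp(r * tt)), 1, tolerance = 0.05)

  exact <- simulate_bd_exact(init, beta, delta, t = tt, n_reps = 300, seed = 32)
  exact_var <- mean(apply(exact, 1, stats::var))
  expect_lt(abs(exact_var - var_theory), 3 * var_theory * sqrt(2 / 299))
  # tau-leap and exact agree with each other distributionally
  expect_equal(mean(exact), obs_mean, tolerance = 0.05)
})

test_that("census is conserved and extinction is absorbing", {
  lib <- geometric_library(30, 1 / 5, seed = 41) # small tags, heavy death
  sim <- simulate_bd(lib, beta = 0.005, delta = 0.2, t = 30, dt = 0.01,
                     n_reps = 5, record_times = seq(0, 30, by = 5),
                     record_counts = TRUE, seed = 42)
  for (i in seq_along(sim$record_times)) {
    expect_equal(colSums(sim$counts[[i]]),
                 dplyr::filter(sim$census, .data$time == sim$record_times[i])$census)
    expect_true(all(sim$counts[[i]] >= 0))
  }
  # once a tag hits zero it stays zero
  for (rep in 1:5) {
    alive <- vapply(sim$counts, function(m) m[, rep] > 0, logical(30))
    dead_then_alive <- apply(alive, 1, function(x) any(diff(x) > 0))
    expect_false(any(dead_then_alive))
  }
})

test_that("multinomial bottlenecks preserve expected composition", {
  only <- multinomial_bottleneck(c(a = 0, b = 500, c = 0), 100, seed = 1)
  expect_equal(unname(only), c(0, 100, 0))
  expect_error(multinomial_bottleneck(c(0, 0), 10), "empty population")

  set.seed(2)
  probs <- c(0.5, 0.3, 0.15, 0.05)
  draws <- replicate(400, multinomial_bottleneck(probs * 1000, 200))
  for (i in seq_along(probs)) {
    se <- stats::sd(draws[i, ]) / sqrt(ncol(draws))
    expect_lt(abs(mean(draws[i, ]) - 200 * probs[i]), 3 * se)
  }

  # founder size of a sampled profile estimates the sample size
  set.seed(3)
  k <- 500
  tags <- sprintf("t%03d", 1:k)
  ref <- reference_profile(tibble::tibble(tag = tags, count = rep(10, k)))
  inv <- replicate(150, {
    drawn <- multinomial_bottleneck(rep(10, k), 1000)
    1 / founder_size(tibble::tibble(tag = tags, count = drawn), ref)$value
  })
  se <- stats::sd(inv) / sqrt(length(inv))
  expect_lt(abs(mean(inv) - 1 / 1000), 3 * se)
})

test_that("rate heterogeneity inflates growth as expected", {
  lib <- tibble::tibble(tag = sprintf("t%03d", 1:200), count = rep(50, 200))
  n0 <- sum(lib$count)
  # tight heterogeneity: indistinguishable from homogeneous mean behavior
  tight <- simulate_bd(lib, 0.03, 0.01, t = 60, dt = 0.01, n_reps = 30,
                       rate_sd = 5e-4, seed = 51)
  fin <- colSums(tight$final_counts)
  expect_equal(mean(fin) / (n0 * exp(0.02 * 60)), 1, tolerance = 0.05)
  # broad heterogeneity: convexity drives the mean census well above the
  # homogeneous expectation and rate estimates drift
  broad <- simulate_bd(lib, 0.03, 0.01, t = 60, dt = 0.01, n_reps = 30,
                       rate_sd = 1e-2, seed = 52)
  expect_gt(mean(colSums(broad$final_counts)), 1.2 * n0 * exp(0.02 * 60))
})

test_that("the in-silico harness collapses correctly without bottlenecks", {
  ex <- run_insilico_experiment(beta = 0.02, delta = 0.01, t = 30, k = 50,
                                prob = 1 / 50, n_iterations = 10,
                                inoculum_sizes = numeric(0),
                                sample_sizes = numeric(0), seed = 61)
  expect_equal(ex$estimates$nb_uncorrected, ex$estimates$nb_ideal)
  expect_equal(ex$estimates$nb_corrected, ex$estimates$nb_ideal)
  expect_equal(ex$correction, 0)
})
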
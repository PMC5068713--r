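test_that("the deterministic recursion has the expected fixed points", {
  hw <- c(0.25, 0.5, 0.25)
  expect_equal(deterministic_recursion(hw, 0, 0.5), hw)
  # lethal 2n = 8: kill the class and renormalise by 0.75
  expect_equal(deterministic_recursion(hw, 1, 0.5), c(0, 2 / 3, 1 / 3))

  # neutral fair meiosis reproduces the assortment expectation at p = g4
  set.seed(3)
  for (i in 1:10) {
    f <- as.vector(rmultinom(1, 100, c(1, 2, 1) / 4)) / 100
    out <- deterministic_recursion(f, 0, 0.5)
    p <- f[1] + 0.5 * f[2]
    expect_equal(out, unname(expected_karyotype_freqs(p)), tolerance = 1e-12)
  }
})

test_that("the recursion conserves probability mass", {
  set.seed(17)
  for (i in 1:30) {
    f <- runif(3); f <- f / sum(f)
    out <- deterministic_recursion(f, runif(1), runif(1))
    expect_lt(abs(sum(out) - 1), 1e-12)
    expect_true(all(out >= 0))
  }
  expect_error(deterministic_recursion(c(1, 0, 0), 1, 0.5), "lethal")
})

test_that("interior equilibria lie on the drive-selection balance manifold", {
  # s * (1 - g5) = 1 - 2k admits an interior equilibrium; iterate to it
  s <- 0.6; k <- 0.35
  eq <- equilibrium_freqs(s, k, init = c(0.2, 0.5, 0.3))
  expect_true(eq$converged)
  expect_equal(deterministic_recursion(eq$freqs, s, k), eq$freqs, tolerance = 1e-8)
  g5 <- eq$freqs[3] + k * eq$freqs[2]
  expect_equal(s * (1 - g5), 1 - 2 * k, tolerance = 1e-4)

  # fair meiosis with selection has no interior equilibrium: the extra
  # chromosome sweeps toward fixation
  eq2 <- equilibrium_freqs(0.5, 0.5, init = c(0.25, 0.5, 0.25), max_iter = 2e5)
  expect_gt(eq2$freqs[3], 0.99)
})

test_that("simulated trajectories are reproducible and conserve population size", {
  cfg <- sim_config(120, 8, c(30, 60, 30), selection_s = 0.3,
                    distortion_k = 0.45, replicates = 2, random_seed = 42)
  a <- simulate_karyotypes(cfg)
  b <- simulate_karyotypes(cfg)
  expect_identical(a$c8, b$c8)
  expect_identical(a$c10, b$c10)
  expect_true(all(a$c8 + a$c9 + a$c10 == 120))
  expect_equal(nrow(a), 2 * 9)
})

test_that("absorbing and forced-transmission regimes behave as expected", {
  # lethal 2n = 8: the class never reappears
  cfg <- sim_config(100, 10, c(0, 100, 0), selection_s = 1, random_seed = 1)
  tr <- simulate_karyotypes(cfg)
  expect_true(all(tr$c8 == 0))

  # full distortion from an all-heterozygote population: first generation all 2n = 10
  cfg2 <- sim_config(100, 1, c(0, 100, 0), distortion_k = 1, random_seed = 2)
  tr2 <- simulate_karyotypes(cfg2)
  expect_equal(tr2$c10[tr2$generation == 1], 100)

  expect_error(sim_config(1, 5, c(1, 0, 0)), "population_size")
  cfg3 <- sim_config(50, 3, c(50, 0, 0), selection_s = 1)
  expect_error(simulate_karyotypes(cfg3), "cannot reproduce")
})

test_that("neutral simulation shows no directional trend in gamete frequency", {
  cfg <- sim_config(100, 50, c(25, 50, 25), selection_s = 0, distortion_k = 0.5,
                    replicates = 400, random_seed = 7)
  tr <- simulate_karyotypes(cfg)
  n <- tr$c8 + tr$c9 + tr$c10
  tr$p_hat <- (2 * tr$c8 + tr$c9) / (2 * n)
  # per-replicate slopes are independent units (the mean trajectory itself is
  # an autocorrelated random walk, so a naive regression on it overrejects)
  slopes <- vapply(split(tr, tr$replicate), function(d) {
    unname(coef(lm(p_hat ~ generation, data = d))["generation"])
  }, numeric(1))
  expect_gt(t.test(slopes)$p.value, 0.05)
  expect_lt(abs(mean(tr$p_hat[tr$generation == 50]) - 0.5), 0.02)
})

test_that("model fitting recovers null parameters from Hardy-Weinberg counts", {
  fit_s <- fit_karyotype_model(c(25, 50, 25), "selection_only")
  expect_equal(unname(fit_s$estimates["s"]), 0, tolerance = 1e-9)
  fit_k <- fit_karyotype_model(c(25, 50, 25), "distortion_only")
  expect_equal(unname(fit_k$estimates["k"]), 0.5, tolerance = 1e-6)
  fit_j <- fit_karyotype_model(c(25, 50, 25), "joint")
  expect_equal(unname(fit_j$estimates["s"]), 0, tolerance = 1e-4)
  expect_equal(unname(fit_j$estimates["k"]), 0.5, tolerance = 1e-4)
})

test_that("the joint fit is saturated: fitted probabilities match the data", {
  fit <- fit_karyotype_model(c(16, 77, 36), "joint")
  expect_equal(unname(fit$fitted_probs), c(16, 77, 36) / 129, tolerance = 1e-4)
  expect_true(fit$identifiable)
  expect_true(fit$stationarity_assumed)
  # self-consistency: the fitted parameters reproduce the observed state as a
  # one-generation stationary point
  est <- fit$estimates
  expect_equal(deterministic_recursion(c(16, 77, 36) / 129, est[["s"]], est[["k"]]),
               c(16, 77, 36) / 129, tolerance = 1e-4)
})

test_that("selection is recoverable with a known parental generation", {
  par_f <- c(16, 77, 36) / 129
  probs <- deterministic_recursion(par_f, 0.4, 0.5)
  set.seed(55)
  obs <- as.integer(rmultinom(1, 1e5, probs))
  fit <- fit_karyotype_model(obs, "selection_only", parental_freqs = par_f)
  expect_lt(abs(unname(fit$estimates["s"]) - 0.4), 0.02)
  expect_false(fit$stationarity_assumed)
})

test_that("distortion is unidentifiable without heterozygous parents", {
  expect_error(fit_karyotype_model(c(30, 0, 70), "distortion_only",
                                   parental_freqs = c(0.5, 0, 0.5)),
               "unidentifiable")
})
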
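# Coalescent simulator: model arithmetic, neutral expectations against
# closed-form coalescent theory, seed reproducibility, sweep conditioning
# and admixture-pulse bookkeeping.

test_that("encoded demographic model reproduces the fitted divergence", {
  m <- build_model()
  expect_equal(m$divergence_time_years, 44588 + 9419)
  expect_equal(round(m$divergence_time_years / 1000), 54)
  expect_error(build_model(list(nT1 = -1)), "positive")
  expect_error(build_model(list(T1 = 2e4)), "epoch times")
  # degenerate configuration: equal sizes, zero migration
  m0 <- build_model(list(m11 = 0, m12 = 0, m21 = 0, m22 = 0))
  spec <- sweepintro:::engine_spec(m0)
  expect_true(all(spec$mig == 0))
  expect_true(all(spec$events$x[spec$events$kind == 1] == 0))
})

test_that("single-population neutral diversity matches 4*N*mu", {
  set.seed(11)
  N <- 10000; L <- 1e5; mu <- 1e-8; nreps <- 150; n <- 10
  ev <- data.frame(time = numeric(0), kind = integer(0), a = integer(0),
                   b = integer(0), x = numeric(0), record = logical(0))
  sim <- sweepintro:::.cpp_sim_coalescent(L, mu, 1e-8, rep(0L, n), 1L, N,
                                          matrix(0, 1, 1), ev, NULL,
                                          as.integer(nreps), 1L)
  k <- sim$counts[, 1]
  pi_rep <- tapply(k * (n - k) / choose(n, 2), sim$rep, sum)
  pi_rep <- c(pi_rep, rep(0, nreps - length(pi_rep)))
  expect_lt(abs(mean(pi_rep) - 4 * N * mu * L),
            3 * sd(pi_rep) / sqrt(nreps))
  # Watterson's estimator agrees too
  S_rep <- tabulate(sim$rep, nreps)
  a_n <- sum(1 / seq_len(n - 1))
  expect_lt(abs(mean(S_rep) / a_n - 4 * N * mu * L),
            3 * sd(S_rep / a_n) / sqrt(nreps))
})

test_that("two-deme island model matches closed-form coalescent times", {
  # symmetric 2-deme island model: E[T_within] = 4N, E[T_between] = 4N + 1/(2m)
  set.seed(12)
  N <- 1000; m <- 0.005; L <- 5e4; mu <- 1e-8; nreps <- 800
  ev <- data.frame(time = 1e7, kind = 2L, a = 1L, b = 0L, x = 1,
                   record = FALSE)
  mig <- matrix(c(0, m, m, 0), 2, 2)
  sim <- sweepintro:::.cpp_sim_coalescent(L, mu, 0, c(0L, 0L, 1L, 1L), 2L,
                                          c(N, N), mig, ev, NULL,
                                          as.integer(nreps), 0L)
  g <- sim$geno
  dw <- (sum(g[, 1] != g[, 2]) + sum(g[, 3] != g[, 4])) / (2 * nreps)
  db <- (sum(g[, 1] != g[, 3]) + sum(g[, 2] != g[, 4])) / (2 * nreps)
  expect_lt(abs(dw - 2 * mu * L * 4 * N), 0.15)          # expected 4.0
  expect_lt(abs(db - 2 * mu * L * (4 * N + 1 / (2 * m))), 0.2)  # expected 4.1
})

test_that("simulations are reproducible under a fixed seed", {
  m <- build_model()
  a <- simulate_neutral(m, test_samples, 1e5, seed = 99)[[1]]
  b <- simulate_neutral(m, test_samples, 1e5, seed = 99)[[1]]
  expect_identical(a$positions, b$positions)
  expect_identical(a$alleles, b$alleles)
  sc <- sweep_scenario(0.04, 0.8, 100)
  p1 <- simulate_sweep(m, sc, test_samples, 1e5, seed = 7)
  p2 <- simulate_sweep(m, sc, test_samples, 1e5, seed = 7)
  expect_identical(p1$alleles, p2$alleles)
  expect_identical(attr(p1, "origin_gen"), attr(p2, "origin_gen"))
})

test_that("sweep conditioning hits the requested end frequency", {
  m <- build_model()
  set.seed(21)
  # trajectory-level check is cheap: realized present-day frequency is the
  # sweep-conclusion frequency blurred by drift plus binomial sampling
  fr <- replicate(100, {
    traj <- sweep_trajectory(m, sweep_scenario(0.03, 0.8, 100))
    rbinom(1, 2 * test_samples[["target"]], traj[1]) /
      (2 * test_samples[["target"]])
  })
  expect_lt(abs(mean(fr) - 0.8), 0.05)
  # and the full simulated panel records a consistent realized frequency
  pan <- simulate_sweep(m, sweep_scenario(0.04, 0.8, 100), test_samples,
                        1e5, seed = 22)
  f <- attr(pan, "focal_index")
  expect_equal(mean(panel_subset(pan, "target")$alleles[, f]),
               attr(pan, "realized_freq"))
})

test_that("unattainable sweep scenarios raise an explicit error", {
  m <- build_model()
  set.seed(23)
  # s too small: the backward decline cannot reach loss inside the
  # divergence-time cap
  expect_error(
    sweep_trajectory(m, sweep_scenario(1e-4, 0.8, 400),
                     max_origin_gens = 500, max_attempts = 5),
    "unattainable")
  expect_error(sweep_scenario(-0.1, 0.5, 100), "positive")
  expect_error(sweep_scenario(0.02, 1.2, 100), "end_freq")
})

test_that("admixture-pulse bookkeeping recovers the pulse fraction", {
  m <- build_model()
  # pulse placed in the recent low-migration epoch so that lineage
  # exchange with the comparison population cannot dilute it
  sc <- archaic_scenario(den_frac_target = 0.05, den_frac_comparison = 0,
                         nea_frac = 0, den_time_years = 8000)
  sims <- simulate_archaic(m, sc,
                           samples = c(target = 10, comparison = 5,
                                       outgroup_modern = 5),
                           sequence_length = 2e5, seed = 31, nreps = 120)
  fr <- vapply(sims, function(s) tract_fraction(s$tracts, 1:20, 2e5),
               numeric(1))
  expect_lt(abs(mean(fr) - 0.05), 3 * sd(fr) / sqrt(length(fr)))
  expect_error(archaic_scenario(den_time_years = 5e5), "postdate")
})

test_that("archaic scenario without admixture leaves D centered at zero", {
  m <- build_model()
  sc0 <- archaic_scenario(den_frac_target = 0, den_frac_comparison = 0,
                          nea_frac = 0)
  sims <- simulate_archaic(m, sc0,
                           samples = c(target = 10, comparison = 10,
                                       outgroup_modern = 5),
                           sequence_length = 5e5, seed = 32, nreps = 20)
  D <- vapply(sims, function(s)
    d_statistic(abba_baba_terms(s$sft, "target", "comparison")), numeric(1))
  expect_lt(abs(mean(D)), 3 * sd(D) / sqrt(length(D)) + 0.01)
})
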
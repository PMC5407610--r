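# Sweep, introgression and divergence dating.

test_that("gene-tree divergence is k / (2 mu L) with exact Poisson CI", {
  ci <- gene_tree_divergence(span = 1e5, mu = 1e-9, differences = 200)
  expect_equal(ci$point, 1e6)
  # zero differences: time 0 with lower bound 0
  ci0 <- gene_tree_divergence(span = 1e4, mu = 1e-9, differences = 0)
  expect_equal(ci0$point, 0)
  expect_equal(ci0$lower, 0)
  expect_gt(ci0$upper, 0)
  # allele-vector interface counts pairwise differences
  ci2 <- gene_tree_divergence(c(0, 1, 1, NA, 0), c(0, 0, 1, 1, 1),
                              span = 1000, mu = 1e-9)
  expect_equal(ci2$point, 2 / (2 * 1e-9 * 1000))
  expect_error(gene_tree_divergence(span = 0, differences = 5), "span")
})

test_that("Poisson interval matches the canonical exact test", {
  for (k in c(1, 7, 200)) {
    ci <- gene_tree_divergence(span = 1e5, mu = 1e-9, differences = k)
    pt <- stats::poisson.test(k)$conf.int
    expect_equal(ci$lower * 2e-4, pt[1], tolerance = 1e-9)
    expect_equal(ci$upper * 2e-4, pt[2], tolerance = 1e-9)
  }
})

test_that("gene-tree time is linear in k and inversely linear in mu, span", {
  for (k in c(10, 50)) for (mu in c(0.5e-9, 1e-9)) for (L in c(1e4, 1e5)) {
    expect_equal(gene_tree_divergence(span = L, mu = mu,
                                      differences = k)$point,
                 k / (2 * mu * L))
  }
})

test_that("population divergence subtracts archaic coalescent waiting", {
  expect_equal(population_divergence(997000, 2580, 25), 868000)
  expect_equal(population_divergence(5e5, 0, 25), 5e5)
  expect_equal(population_divergence(1e4, 1e4, 25), 0)  # floored
})

test_that("sweep-age likelihood is reproducible and degenerate grids pass through", {
  m <- build_model()
  obs <- c(freq = 0.8, share_length = 5e4)
  one <- sweep_age_mle(obs, m, 0.04, age_grid = 250)
  expect_equal(one$age, 250)
  expect_equal(one$ci$lower, 250)
  a <- sweep_age_mle(obs, m, 0.04, age_grid = c(150, 250), n_reps = 6,
                     samples = test_samples, sequence_length = 1e5,
                     seed = 41)
  b <- sweep_age_mle(obs, m, 0.04, age_grid = c(150, 250), n_reps = 6,
                     samples = test_samples, sequence_length = 1e5,
                     seed = 41)
  expect_equal(a$loglik, b$loglik)
})

test_that("introgression window collapses when survival must be certain", {
  m <- build_model()
  w <- introgression_window(480, m, survival_threshold = 1)
  expect_equal(w$earliest_gens, 480)
  expect_equal(w$latest_gens, 480)
})

test_that("introgression window matches a direct drift-simulation oracle", {
  # constant-size target population (all epochs 2445 diploids)
  m <- build_model(list(nT1 = 2445, nT2 = 2445, nT3 = 2445))
  onset <- 300
  cands <- onset + seq(0, 120, by = 10)
  w <- introgression_window(onset, m, survival_threshold = 0.05,
                            candidate_gens = cands, n_reps = 3000,
                            seed = 42)
  # oracle: independent Wright-Fisher survival simulation
  set.seed(4242)
  surv <- vapply(cands, function(t0) {
    alive <- 0
    for (r in 1:3000) {
      x <- 1 / (2 * 2445)
      dead <- FALSE
      for (g in seq_len(t0 - onset)) {
        x <- rbinom(1, 2 * 2445, x) / (2 * 2445)
        if (x <= 0) { dead <- TRUE; break }
        if (x >= 1) break
      }
      if (!dead) alive <- alive + 1
    }
    alive / 3000
  }, numeric(1))
  oracle_earliest <- max(cands[surv >= 0.05])
  expect_lte(abs(w$earliest_gens - oracle_earliest), 10)  # one grid step
  expect_equal(w$latest_gens, onset)
  expect_true(all(diff(w$survival$survival) <= 0.05))  # decays with age
})
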
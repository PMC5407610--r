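# Composite-score machinery: density training, naive-Bayes combination,
# empirical p-values, q-values and region aggregation.

test_that("training grid covers 60 scenario cells", {
  g <- cms_scenario_grid()
  expect_equal(nrow(g), 60)
  expect_equal(sort(unique(g$s)), c(0.02, 0.03, 0.04))
  expect_equal(sort(unique(g$end_time_gens)), c(0, 100, 200, 300, 400))
  expect_equal(sort(unique(g$end_freq)), c(0.2, 0.4, 0.6, 0.8))
})

fake_scores <- function(n, seed) {
  set.seed(seed)
  data.frame(fst = rnorm(n), delta_daf = rnorm(n), ihs_raw = rnorm(n),
             delta_ihh_raw = rnorm(n), xpehh_raw = rnorm(n))
}

test_that("identical ensembles give the flat-ratio closed form", {
  x <- fake_scores(500, 1)
  d <- train_cms(x, x)
  expect_true(all(vapply(d$dists, function(dd)
    isTRUE(all.equal(dd$null, dd$alt)), logical(1))))
  cms <- cms_score(x[1:10, ], d, prior = 1e-4)
  expect_equal(cms, rep(5 * log(1e-4), 10))
  expect_true(all(cms <= 0))
  expect_error(train_cms(x[0, ], x), "non-empty")
})

test_that("composite score responds to a raised likelihood ratio", {
  x <- fake_scores(2000, 2)
  d <- train_cms(x, x)
  # raise the alternative density of one fst bin by a factor of 10
  bin <- 30
  d$dists$fst$alt[bin] <- 10 * d$dists$fst$alt[bin]
  xx <- x[1, ]
  xx$fst <- mean(d$dists$fst$breaks[bin + 0:1])  # a value in that bin
  pri <- 1e-4
  got <- cms_score(xx, d, pri)
  expected_shift <- log(10 * pri / (10 * pri + 1 - pri)) - log(pri)
  expect_equal(got - 5 * log(pri), expected_shift, tolerance = 1e-9)
  expect_equal(expected_shift, 2.30, tolerance = 0.005)
})

test_that("composite score is monotone in each component likelihood ratio", {
  null_s <- fake_scores(3000, 3)
  alt_s <- fake_scores(600, 4)
  alt_s[] <- lapply(alt_s, function(v) v + 2)  # shifted alternative
  d <- train_cms(null_s, alt_s)
  for (cmp in sweepintro:::cms_components) {
    probe <- fake_scores(2, 5)
    probe[] <- lapply(probe, function(v) rep(0, 2))
    probe[[cmp]] <- c(0, 2)    # higher value = higher LR under the shift
    sc <- cms_score(probe, d)
    expect_gt(sc[2], sc[1])
  }
})

test_that("missing components rescale to stay comparable", {
  x <- fake_scores(1000, 6)
  d <- train_cms(x, x)
  probe <- x[1, ]
  probe$ihs_raw <- NA; probe$xpehh_raw <- NA; probe$delta_ihh_raw <- NA
  expect_equal(cms_score(probe, d), 5 * log(1e-4))  # 5/2 rescale of 2 terms
  probe2 <- probe
  probe2$fst <- NA; probe2$delta_daf <- NA
  expect_true(is.na(cms_score(probe2, d)))
})

test_that("empirical p-values count the null upper tail with a pseudo-count", {
  expect_equal(empirical_pvalues(-55, c(-50, -60, -70)), 0.5)
  expect_equal(empirical_pvalues(-80, c(-50, -60, -70)), 1)
  expect_equal(empirical_pvalues(-40, c(-50, -60, -70)), 1 / 4)
  expect_equal(empirical_pvalues(-60, c(-50, -60, -70)), 3 / 4)  # ties count
  expect_true(is.na(empirical_pvalues(NA, c(-1, -2))))
  expect_error(empirical_pvalues(-1, numeric(0)), "empty")
})

test_that("q-values follow Benjamini-Hochberg step-up", {
  expect_equal(fdr_qvalues(c(0.001, 0.02, 0.03, 0.04)),
               c(0.004, 0.04, 0.04, 0.04))
  expect_equal(fdr_qvalues(0.01), 0.01)
  expect_equal(fdr_qvalues(rep(1, 5)), rep(1, 5))
  p <- runif(50)
  q <- fdr_qvalues(p)
  expect_true(all(q >= p - 1e-12))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("region aggregation takes the window maximum and merges tops", {
  w <- partition_windows(1e6, 2e5)
  pos <- c(1e5, 3e5, 3.5e5, 5e5, 9e5)
  cms <- c(-50, -60, -45, -70, -30)
  reg <- region_cms(pos, cms, w, top_fraction = 0.4)
  expect_equal(reg$windows$cms_max, c(-50, -45, -70, NA, -30))
  expect_equal(reg$windows$n_sites, c(1L, 2L, 1L, 0L, 1L))
  expect_equal(which(reg$windows$rank == 1), 5)
  expect_equal(sum(reg$windows$top), 1)  # floor(4 * 0.4) = 1
  # single site per window: the window score is the site score
  reg1 <- region_cms(c(1e5, 3e5), c(-12, -13), w)
  expect_equal(reg1$windows$cms_max[1:2], c(-12, -13))
})
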
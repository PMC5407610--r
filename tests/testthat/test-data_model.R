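# Containers, window bookkeeping and exact binomial intervals.

test_that("window partitioning tiles the chromosome", {
  expect_equal(nrow(partition_windows(1e6, 2e5)), 5)
  w <- partition_windows(1000001, 2e5)
  expect_equal(nrow(w), 6)
  expect_equal(w$end[6] - w$start[6] + 1, 1)
  expect_error(partition_windows(1e6, 0), "positive")
  # reported starts are 1 (mod width), and the 800-kb stretch
  # 231200001-232000000 decomposes into exactly 4 consecutive windows
  w2 <- partition_windows(232000000, 2e5)
  expect_true(all((w2$start - 1) %% 2e5 == 0))
  hit <- which(w2$start >= 231200001 & w2$end <= 232000000)
  expect_equal(length(hit), 4)
  expect_equal(diff(hit), rep(1, 3))
  expect_equal(w2$start[hit[1]], 231200001)
  expect_equal(w2$end[hit[4]], 232000000)
})

test_that("window tiling conserves sites", {
  set.seed(1)
  for (r in 1:5) {
    L <- sample.int(3e6, 1)
    width <- sample(c(5e4, 2e5, 123457), 1)
    w <- partition_windows(L, width)
    pos <- sort(sample.int(L, 200))
    wi <- assign_windows(pos, w)
    expect_false(anyNA(wi))
    expect_true(all(pos >= w$start[wi] & pos <= w$end[wi]))
  }
})

test_that("adjacent selected windows merge into maximal runs", {
  w <- partition_windows(2e6, 2e5)
  expect_equal(nrow(merge_adjacent(w, rep(FALSE, 10))), 0)
  sel <- seq_len(10) %in% c(3, 4, 5, 9)
  sc <- c(NA, NA, -60, -45, -50, NA, NA, NA, -70, NA)
  m <- merge_adjacent(w, sel, sc)
  expect_equal(nrow(m), 2)
  expect_equal(m$n_windows, c(3, 1))
  expect_equal(m$score[1], -45)    # interval aggregate is the member max
  expect_equal(m$start[1], w$start[3])
  expect_equal(m$end[1], w$end[5])
})

test_that("exact binomial intervals match printed frequencies", {
  ci <- exact_binomial_ci(1, 54)
  expect_equal(round(100 * ci$lower, 2), 0.05)
  expect_equal(round(100 * ci$upper, 2), 9.89)
  ci2 <- exact_binomial_ci(1, 124)
  expect_equal(round(100 * ci2$lower, 2), 0.02)
  expect_equal(round(100 * ci2$upper, 2), 4.41)
  expect_equal(exact_binomial_ci(0, 10)$lower, 0)
  expect_equal(exact_binomial_ci(10, 10)$upper, 1)
  expect_error(exact_binomial_ci(5, 4), "successes")
})

test_that("exact binomial endpoints satisfy the defining tail equations", {
  set.seed(2)
  for (r in 1:20) {
    n <- sample(5:200, 1)
    k <- sample.int(n - 1, 1)
    ci <- exact_binomial_ci(k, n, 0.95)
    # at the lower bound, P(X >= k) = 0.025; at the upper, P(X <= k) = 0.025
    expect_lt(abs(1 - pbinom(k - 1, n, ci$lower) - 0.025), 1e-9)
    expect_lt(abs(pbinom(k, n, ci$upper) - 0.025), 1e-9)
  }
})

test_that("allele counts handle saturation, missingness and reordering", {
  pan <- toy_panel()
  ac <- allele_counts(pan, "target")
  expect_equal(ac$derived_count[3], 4)           # all target haplotypes
  expect_equal(ac$chromosome_count[3], 4)
  # 46 of 54 derived is an 85.2% frequency
  expect_equal(round(100 * 46 / 54, 1), 85.2)
  # one missing haplotype: complete-case denominator
  alle <- pan$alleles
  alle[1, 2] <- NA
  pan2 <- haplotype_panel(pan$chrom, pan$positions, alle, pan$individuals,
                          pan$populations)
  ac2 <- allele_counts(pan2, "target")
  expect_equal(ac2$chromosome_count[2], 3)
  expect_equal(ac2$derived_count[2], 3)
  expect_error(allele_counts(pan, "nope"), "unknown population")
  # invariance under haplotype reordering
  set.seed(3)
  ord <- sample(nrow(pan$alleles))
  pan3 <- haplotype_panel(pan$chrom, pan$positions,
                          pan$alleles[ord, ], pan$individuals[ord],
                          pan$populations)
  expect_equal(allele_counts(pan3, "target"), allele_counts(pan, "target"))
})

test_that("panel validation rejects malformed input", {
  expect_error(haplotype_panel("c", c(5, 5), matrix(0, 2, 2), c("a", "a"),
                               c(a = "p")), "strictly increasing")
  expect_error(haplotype_panel("c", c(1, 5), matrix(2, 2, 2), c("a", "a"),
                               c(a = "p")), "0, 1 or NA")
  expect_error(haplotype_panel("c", c(1, 5), matrix(0, 2, 2), c("a", "b"),
                               c(a = "p")), "population")
})

test_that("percentile bootstrap interval brackets the point estimate", {
  ci <- percentile_ci(0.5, c(0.4, 0.45, 0.5, 0.55, 0.6))
  expect_lte(ci$lower, ci$point)
  expect_gte(ci$upper, ci$point)
})
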
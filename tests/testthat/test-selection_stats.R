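# FST estimators, frequency contrasts, PBS, EHH-family statistics.

test_that("Hudson site FST matches hand-evaluated cases", {
  expect_equal(site_fst(8, 10, 2, 10), 0.4771, tolerance = 1e-4)
  expect_equal(round(site_fst(38, 54, 0, 124), 2), 0.70)
  # no differentiation at large n
  expect_lt(abs(site_fst(5000, 10000, 5000, 10000)), 1e-3)
  expect_true(is.na(site_fst(0, 10, 0, 10)))   # both monomorphic ancestral
  expect_error(site_fst(1, 1, 2, 10), "2 chromosomes")
})

test_that("Hudson FST equals a symbol-by-symbol oracle on random counts", {
  oracle <- function(d1, n1, d2, n2) {
    p1 <- d1 / n1; p2 <- d2 / n2
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    num / den
  }
  set.seed(5)
  for (r in 1:1000) {
    n1 <- sample(2:200, 1); n2 <- sample(2:200, 1)
    d1 <- sample(0:n1, 1); d2 <- sample(0:n2, 1)
    if ((d1 == 0 && d2 == 0) || (d1 == n1 && d2 == n2)) next
    expect_equal(site_fst(d1, n1, d2, n2), oracle(d1, n1, d2, n2))
  }
})

test_that("genome-wide FST is the ratio of sums, not the mean of ratios", {
  d1 <- c(8, 30); n1 <- 40; d2 <- c(2, 10); n2 <- 40
  num <- den <- 0
  for (i in 1:2) {
    p1 <- d1[i] / n1; p2 <- d2[i] / n2
    num <- num + (p1 - p2)^2 - p1 * (1 - p1) / 39 - p2 * (1 - p2) / 39
    den <- den + p1 * (1 - p2) + p2 * (1 - p1)
  }
  expect_equal(genomewide_fst(d1, n1, d2, n2), num / den)
  expect_false(isTRUE(all.equal(genomewide_fst(d1, n1, d2, n2),
                                mean(site_fst(d1, n1, d2, n2)))))
  # identical frequencies: zero up to the finite-sample correction
  expect_lt(abs(genomewide_fst(c(5000, 900), 10000, c(5000, 900), 10000)),
            1e-3)
  expect_error(genomewide_fst(0, 10, 0, 10), "denominator")
})

test_that("Weir-Cockerham estimator agrees with Hudson for balanced sizes", {
  # for equal sample sizes the two estimators are close but not identical
  set.seed(6)
  d1 <- rbinom(200, 50, 0.3); d2 <- rbinom(200, 50, 0.35)
  h <- genomewide_fst(d1, 50, d2, 50, "hudson")
  w <- genomewide_fst(d1, 50, d2, 50, "wc")
  expect_lt(abs(h - w), 0.02)
})

test_that("delta DAF subtracts frequencies and flips under population swap", {
  expect_equal(delta_daf(0.852, 0.427), 0.425)
  expect_equal(delta_daf(0.5, 0.5), 0)
  expect_equal(delta_daf(0.70, 0.0), 0.70)
  set.seed(7)
  a <- runif(50); b <- runif(50)
  expect_equal(delta_daf(a, b), -delta_daf(b, a))
  expect_equal(site_fst(round(a * 30), 30, round(b * 40), 40),
               site_fst(round(b * 40), 40, round(a * 30), 30))
})

test_that("PBS isolates the target branch", {
  expect_equal(pbs(0, 0, 0), 0)
  expect_equal(pbs(0.1, 0.1, 0.1), 0.05268, tolerance = 1e-4)
  expect_true(is.na(pbs(1, 0.1, 0.1)))
  expect_equal(pbs(-0.02, 0, 0), 0)    # negative FST clamps to zero
})

test_that("EHH profile follows the pair-counting definition", {
  pan <- toy_panel()
  # core site 3 has 6 carriers; at site 4 they split into groups of 4 and 2
  pr <- ehh_profile(pan, 3, allele = 1, cutoff = 0)
  e4 <- pr$ehh[pr$site == 4]
  expect_equal(e4, (choose(4, 2) + choose(2, 2)) / choose(6, 2))
  # two identical pairs among 4 carriers: EHH = 2 * C(2,2-pairs) / C(4,2)
  pan2 <- haplotype_panel("chr1", c(100, 200),
                          rbind(c(1, 1), c(1, 1), c(1, 0), c(1, 0),
                                c(0, 0), c(0, 1)),
                          rep(c("a", "b", "c"), each = 2),
                          c(a = "p", b = "p", c = "p"))
  pr2 <- ehh_profile(pan2, 1, allele = 1, cutoff = 0)
  expect_equal(pr2$ehh[pr2$site == 2], 2 / 6)
  # carriers all distinct -> EHH 0; all identical -> EHH 1
  pan3 <- haplotype_panel("chr1", c(100, 200),
                          rbind(c(1, 1), c(1, 0), c(0, 0), c(0, 0)),
                          rep(c("a", "b"), each = 2), c(a = "p", b = "p"))
  pr3 <- ehh_profile(pan3, 1, allele = 1, cutoff = 0)
  expect_equal(pr3$ehh[pr3$site == 2], 0)
  pr4 <- ehh_profile(pan3, 1, allele = 0, cutoff = 0)
  expect_equal(pr4$ehh[pr4$site == 2], 1)
  expect_error(ehh_profile(pan3, 2, allele = 1), "2 carrier")
  # EHH is non-increasing outward
  set.seed(8)
  rp <- random_panel(12, 30)
  core <- 15
  if (sum(rp$alleles[, core] == 1) >= 2) {
    pr5 <- ehh_profile(rp, core, 1, cutoff = 0)
    right <- pr5$ehh[pr5$site >= core]
    left <- rev(pr5$ehh[pr5$site <= core])
    expect_true(all(diff(right) <= 1e-12))
    expect_true(all(diff(left) <= 1e-12))
  }
})

test_that("iHH integrates EHH over genetic distance", {
  # EHH stays 1 over 0.1 cM (100 kb at 1 cM/Mb) then collapses to 0:
  # carriers identical across the span, then all-distinct splits
  alle <- rbind(c(1, 1, 1, 1, 0, 0),
                c(1, 1, 1, 1, 1, 0),
                c(1, 1, 1, 1, 0, 1),
                c(0, 0, 0, 0, 1, 1))
  pan <- haplotype_panel("chr1", c(1, 2, 50000, 100001, 100002, 100003),
                         alle, rep(c("a", "b"), each = 2),
                         c(a = "p", b = "p"))
  hs <- haplotype_scores(pan, 2)
  # derived carriers identical from site 2 to site 4 (0.1 cM), then EHH
  # drops to 0 within ~1 bp; the integral is ~0.1 cM
  expect_equal(hs$ihh_d, 0.1, tolerance = 0.01)
  # symmetric profiles give zero iHS and delta-iHH
  alle_sym <- rbind(c(1, 1, 1), c(1, 1, 1), c(0, 0, 0), c(0, 0, 0))
  pan_sym <- haplotype_panel("chr1", c(1000, 2000, 3000), alle_sym,
                             rep(c("a", "b"), each = 2),
                             c(a = "p", b = "p"))
  hs2 <- haplotype_scores(pan_sym, 2)
  expect_equal(hs2$ihs_raw, 0)
  expect_equal(hs2$delta_ihh_raw, 0)
})

test_that("iHH is invariant under haplotype permutation", {
  set.seed(9)
  rp <- random_panel(12, 40)
  core <- 20
  hs <- haplotype_scores(rp, core)
  ord <- sample(nrow(rp$alleles))
  rp2 <- haplotype_panel(rp$chrom, rp$positions, rp$alleles[ord, ],
                         rp$individuals[ord], rp$populations)
  hs2 <- haplotype_scores(rp2, core)
  expect_equal(hs$ihh_a, hs2$ihh_a)
  expect_equal(hs$ihh_d, hs2$ihh_d)
})

test_that("XP-EHH is antisymmetric and zero for identical panels", {
  set.seed(10)
  rp <- random_panel(16, 40)
  core <- 20
  x1 <- xpehh_raw(rp, "target", "comparison", core)
  x2 <- xpehh_raw(rp, "comparison", "target", core)
  if (is.finite(x1)) expect_equal(x1, -x2)
  # population A fully homozygous over the region, B diverse -> positive
  alle <- rbind(matrix(rep(c(1, 1, 1, 1, 1), 4), 4, byrow = TRUE),
                rbind(c(1, 0, 1, 0, 1), c(1, 1, 0, 0, 1),
                      c(0, 0, 1, 1, 0), c(0, 1, 0, 1, 0)))
  pan <- haplotype_panel("chr1", c(1000, 2000, 3000, 4000, 5000), alle,
                         rep(c("a", "b", "c", "d"), each = 2),
                         c(a = "target", b = "target",
                           c = "comparison", d = "comparison"))
  x <- xpehh_raw(pan, "target", "comparison", 3)
  expect_gt(x, 0)
})

test_that("score normalisation is exact for the two-point case", {
  expect_equal(normalize_scores(c(-1, 1)), c(-1, 1))
  expect_error(normalize_scores(c(2, 2, 2)), "variance")
  x <- c(1, 2, 3, NA, 4)
  z <- normalize_scores(x)
  expect_true(is.na(z[4]))
  expect_equal(mean(z, na.rm = TRUE), 0)
  zi <- z[is.finite(z)]
  expect_equal(sqrt(mean(zi^2)), 1)    # unit population SD
  # reference moments shift the centre
  z2 <- normalize_scores(x, reference = list(mean = 0, sd = 2))
  expect_equal(z2[1], 0.5)
})
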
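# D / U / D* statistics, S* dynamic programming, admixture-fraction
# estimation and overlap permutation tests.

test_that("D statistic matches hand-evaluated site patterns", {
  # exclusive case sharing gives D = +1
  sft <- make_sft(1, list(target = list(54, 54), comparison = list(0, 124)),
                  archaic = list(denisovan = 1L), outgroup = 0L)
  expect_equal(d_statistic(abba_baba_terms(sft, "target", "comparison")), 1)
  # equal frequencies cancel term by term
  sft2 <- make_sft(1:4, list(target = list(c(5, 9, 0, 54), 54),
                             comparison = list(2 * c(5, 9, 0, 54), 108)),
                   archaic = list(denisovan = c(1L, 1L, 1L, 1L)),
                   outgroup = c(0L, 0L, 0L, 0L))
  expect_equal(d_statistic(abba_baba_terms(sft2, "target", "comparison")), 0,
               tolerance = 1e-12)
  # three-site toy, term-by-term evaluation
  sft3 <- make_sft(1:3, list(target = list(c(1, 0, 1), 2),
                             comparison = list(c(0, 1, 1), 2)),
                   archaic = list(denisovan = c(1L, 1L, 1L)),
                   outgroup = c(0L, 0L, 0L))
  expect_equal(d_statistic(abba_baba_terms(sft3, "target", "comparison")), 0)
  # sites with outgroup-derived or archaic-missing alleles contribute nothing
  sft4 <- make_sft(1:2, list(target = list(c(54, 54), 54),
                             comparison = list(c(0, 0), 124)),
                   archaic = list(denisovan = c(1L, NA)),
                   outgroup = c(1L, 0L))
  tm <- abba_baba_terms(sft4, "target", "comparison")
  expect_equal(tm$term_case, c(0, 0))
  expect_error(d_statistic(tm), "zero D denominator")
})

test_that("D is bounded and antisymmetric under case-control swap", {
  set.seed(11)
  for (r in 1:20) {
    n <- 30
    sft <- make_sft(seq_len(n),
                    list(target = list(rbinom(n, 54, runif(1, .05, .9)), 54),
                         comparison = list(rbinom(n, 124, runif(1, .05, .9)),
                                           124)),
                    archaic = list(denisovan = rbinom(n, 1, 0.6)),
                    outgroup = rbinom(n, 1, 0.1))
    d1 <- d_statistic(abba_baba_terms(sft, "target", "comparison"))
    d2 <- d_statistic(abba_baba_terms(sft, "comparison", "target"))
    expect_lte(abs(d1), 1)
    expect_equal(d1, -d2)
  }
})

test_that("U equals the window-summed D denominator", {
  arcs <- archaic_reps()
  tr <- abba_baba_terms(arcs[[1]]$sft, "target", "comparison")
  w <- u_statistic(tr, partition_windows(1e6, 2e5))
  expect_equal(sum(w$U), sum(tr$term_case + tr$term_ctrl))
  expect_true(all(w$U >= 0))
  # empty-window U is zero and its D undefined
  w2 <- u_statistic(tr[tr$position < 2e5, ], partition_windows(1e6, 2e5))
  expect_equal(w2$U[5], 0)
  expect_true(is.na(w2$D[5]))
})

test_that("block bootstrap collapses for identical blocks", {
  tm <- data.frame(position = c(5e5, 15e5, 25e5, 35e5),
                   term_case = 2, term_ctrl = 1)
  ci <- block_bootstrap_ci(tm, 1e6, replicates = 50)
  expect_equal(ci$lower, ci$upper)
  expect_equal(ci$point, 1 / 3)
  expect_equal(length(attr(ci, "replicates")), 50)
  expect_error(block_bootstrap_ci(tm[1, ]), "2 blocks")
})

test_that("D* divides by the within-U-group spread", {
  # construct windows whose groups are known: U determines the grouping
  set.seed(12)
  n <- 40
  w <- partition_windows(n * 2e5, 2e5)
  w$U <- seq_len(n)           # four groups of ten when n_groups = 4
  w$D <- rnorm(n)
  ds <- dstar_scores(w, n_groups = 4)
  expect_equal(as.integer(table(ds$u_group)), rep(10L, 4))
  for (g in 1:4) {
    ii <- which(ds$u_group == g)
    expect_equal(ds$d_star[ii], ds$D[ii] / sd(ds$D[ii]))
  }
  # a window with D = 0.5 divided by a group spread of 0.25 scores 2.0
  grp_d <- c(0.5, rep(c(0.25, 0.75), c(5, 4)))
  w$D[ds$u_group == 2] <- grp_d * (0.25 / sd(grp_d))
  ds_b <- dstar_scores(w, n_groups = 4)
  ii2 <- which(ds_b$u_group == 2)
  expect_equal(ds_b$d_star[ii2][1],
               w$D[ii2][1] / 0.25)
  # remainder windows go to the lowest-U groups
  w2 <- w[1:42, ]; w2$U <- 42:1; w2$D <- rnorm(42)
  ds2 <- dstar_scores(w2, n_groups = 4)
  expect_equal(as.integer(table(ds2$u_group)), c(11L, 11L, 10L, 10L))
  # degenerate: constant D within a group
  w3 <- w; w3$D <- 0.3
  expect_error(dstar_scores(w3, n_groups = 4), "zero within-group SD")
  # null-calibrated p and q
  ds3 <- dstar_scores(w, n_groups = 4, null_dstar = rnorm(500))
  expect_true(all(ds3$p > 0 & ds3$p <= 1, na.rm = TRUE))
  expect_true(all(ds3$q >= ds3$p - 1e-12, na.rm = TRUE))
})

test_that("S* chain scores match the spec'd dynamic program", {
  mk <- function(pos, targ_hap) {
    n <- length(pos)
    alle <- rbind(targ_hap, rep(0, n), rep(0, n), rep(0, n))
    haplotype_panel("chr1", pos, alle, c("t1", "t1", "c1", "c1"),
                    c(t1 = "target", c1 = "comparison"))
  }
  w <- partition_windows(5e4, 5e4)
  # two congruent candidate sites 2 kb apart
  s2 <- sstar_scan(mk(c(1000, 3000), c(1, 1)), windows = w)
  expect_equal(s2$windows$s_star, 7000)
  # three congruent sites at 2 kb spacing chain twice
  s3 <- sstar_scan(mk(c(1000, 3000, 5000), c(1, 1, 1)), windows = w)
  expect_equal(s3$windows$s_star, 14000)
  # no candidate sites, no score
  s0 <- sstar_scan(mk(c(1000, 3000), c(0, 0)), windows = w)
  expect_true(is.na(s0$windows$s_star))
  # sites closer than the minimum spacing cannot chain
  s1 <- sstar_scan(mk(c(1000, 1005), c(1, 1)), windows = w)
  expect_true(is.na(s1$windows$s_star))
})

test_that("S* dynamic program equals brute force over site subsets", {
  brute <- function(pos, keys, bonus = 5000, mismatch = -10000,
                    min_spacing = 10) {
    m <- length(pos)
    if (m < 2) return(NA_real_)
    best <- -Inf
    for (size in 2:m) {
      for (sub in utils::combn(m, size, simplify = FALSE)) {
        tot <- 0; ok <- TRUE
        for (j in 2:length(sub)) {
          d <- pos[sub[j]] - pos[sub[j - 1]]
          if (d < min_spacing) { ok <- FALSE; break }
          tot <- tot + if (keys[sub[j]] == keys[sub[j - 1]]) bonus + d
                       else mismatch
        }
        if (ok) best <- max(best, tot)
      }
    }
    if (is.finite(best)) best else NA_real_
  }
  set.seed(13)
  for (r in 1:12) {
    n_site <- sample(4:10, 1)
    pos <- sort(sample.int(45000, n_site))
    targ <- rbind(rep(1, n_site),
                  rbinom(n_site, 1, 0.5),
                  rbinom(n_site, 1, 0.3))
    alle <- rbind(targ, matrix(0, 3, n_site))
    pan <- haplotype_panel("chr1", pos, alle,
                           c("t1", "t1", "t2", "c1", "c1", "c2"),
                           c(t1 = "target", t2 = "target",
                             c1 = "comparison", c2 = "comparison"))
    got <- sstar_scan(pan, windows = partition_windows(5e4, 5e4))
    keys <- apply(alle[1:3, , drop = FALSE], 2, paste, collapse = "")
    want <- suppressWarnings(
      max(c(brute(pos, keys),   # haplotype 1 carries every site
            vapply(2:3, function(h) {
              carr <- which(alle[h, ] == 1)
              if (length(carr) < 2) return(NA_real_)
              brute(pos[carr], keys[carr])
            }, numeric(1))), na.rm = TRUE))
    if (!is.finite(want)) want <- NA_real_
    expect_equal(got$windows$s_star, want)
  }
})

test_that("overlap permutation test matches the hypergeometric oracle", {
  set.seed(14)
  scores <- runif(100)
  introgressed <- seq_len(100) %in% sample.int(100, 5)
  out <- overlap_permutation_test(introgressed, scores, top_fraction = 0.1,
                                  replicates = 20000)
  expect_equal(out$n_top, 10)
  # null overlap is hypergeometric: draw 10 of 100 windows, 5 marked
  p_exact <- sum(dhyper(out$observed:5, 5, 95, 10))
  expect_lt(abs(out$p - p_exact), 0.02)
  # no introgressed windows: observed 0 and p = 1
  out0 <- overlap_permutation_test(rep(FALSE, 100), scores, 0.1, 200)
  expect_equal(out0$observed, 0)
  expect_equal(out0$p, 1)
  expect_error(overlap_permutation_test(c(TRUE, FALSE), scores), "match")
})
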
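# Archaic-introgression statistics: the ABBA-BABA D statistic with 1-Mb
# block bootstrap, the window U statistic (D's denominator mass), the
# variance-normalised D*, an S*-style dynamic-programming haplotype scan,
# an f4-ratio admixture-fraction estimator with ghost-source correction,
# and window-overlap permutation tests against selection scans.
#
# Sign convention: POSITIVE D means excess archaic sharing in the CASE
# population.  (The defining sum is over
# p_case (1-p_ctrl) p_arch (1-p_out) - (1-p_case) p_ctrl p_arch (1-p_out);
# sites where the outgroup carries the derived allele are suppressed by
# the (1-p_out) weight.)

#' Per-site ABBA/BABA sharing terms
#'
#' @param sft a [site_frequency_table()] with an archaic track and an
#'   outgroup track.
#' @param case,control population labels.
#' @param archaic archaic track name (e.g. `"denisovan"`).
#' @return data.frame `position`, `term_case`, `term_ctrl` (zero where the
#'   archaic or outgroup allele is missing).
#' @export
abba_baba_terms <- function(sft, case, control, archaic = "denisovan") {
  p1 <- site_freq(sft, case)
  p2 <- site_freq(sft, control)
  p3 <- sft[[paste0("archaic_", archaic)]]
  if (is.null(p3)) stop("archaic track not present: ", archaic)
  p4 <- sft$outgroup
  if (is.null(p4)) stop("outgroup track required")
  tc <- p1 * (1 - p2) * p3 * (1 - p4)
  tk <- (1 - p1) * p2 * p3 * (1 - p4)
  miss <- !is.finite(p1) | !is.finite(p2) | is.na(p3) | is.na(p4)
  tc[miss] <- 0; tk[miss] <- 0
  data.frame(position = sft$position, term_case = tc, term_ctrl = tk)
}

#' D statistic from sharing terms
#'
#' `D = sum(term_case - term_ctrl) / sum(term_case + term_ctrl)`; positive
#' values indicate excess archaic sharing in the case population.
#'
#' @param terms data.frame from [abba_baba_terms()] (possibly several
#'   chromosomes/replicates concatenated).
#' @export
d_statistic <- function(terms) {
  den <- sum(terms$term_case + terms$term_ctrl)
  if (den == 0) stop("no archaic-informative sites (zero D denominator)")
  sum(terms$term_case - terms$term_ctrl) / den
}

#' Block-bootstrap confidence interval for D
#'
#' The genome is cut into fixed blocks (1 Mb by default); blocks are
#' resampled with replacement and D recomputed per replicate; the CI is
#' the percentile interval of the replicate values.
#'
#' @param terms data.frame from [abba_baba_terms()]; if a `block` column
#'   is present it is used, otherwise blocks are derived from `position`
#'   and `block_size` (supply a `chrom`-ed offset upstream when
#'   concatenating chromosomes).
#' @param block_size block width in bp.
#' @param replicates bootstrap replicates.
#' @param level confidence level.
#' @return an `interval_ci` with the replicate values in
#'   `attr(., "replicates")`.
#' @export
block_bootstrap_ci <- function(terms, block_size = 1e6, replicates = 200,
                               level = 0.95) {
  blk <- if (!is.null(terms$block)) terms$block
         else floor((terms$position - 1) / block_size)
  ub <- unique(blk)
  if (length(ub) < 2) stop("need at least 2 blocks for the bootstrap")
  bc <- tapply(terms$term_case, blk, sum)[as.character(ub)]
  bk <- tapply(terms$term_ctrl, blk, sum)[as.character(ub)]
  reps <- vapply(seq_len(replicates), function(i) {
    ii <- sample.int(length(ub), replace = TRUE)
    den <- sum(bc[ii] + bk[ii])
    if (den == 0) return(NA_real_)
    sum(bc[ii] - bk[ii]) / den
  }, numeric(1))
  ci <- percentile_ci(d_statistic(terms), reps, level)
  attr(ci, "replicates") <- reps
  ci
}

#' Window U statistic
#'
#' The denominator mass of D summed per window: the weight of
#' archaic-informative sites, against which D's sampling variance is
#' calibrated.
#'
#' @param terms data.frame from [abba_baba_terms()].
#' @param windows a [partition_windows()] table.
#' @return the window table plus `D`, `U`, `n_sites` (window D is `NA`
#'   where U = 0).
#' @export
u_statistic <- function(terms, windows) {
  wi <- assign_windows(terms$position, windows)
  lev <- factor(wi, levels = seq_len(nrow(windows)))
  sc <- tapply(terms$term_case, lev, sum)
  sk <- tapply(terms$term_ctrl, lev, sum)
  sc[is.na(sc)] <- 0; sk[is.na(sk)] <- 0
  w <- windows
  w$U <- as.numeric(sc + sk)
  w$D <- ifelse(w$U > 0, as.numeric(sc - sk) / w$U, NA_real_)
  w$n_sites <- as.integer(table(lev))
  w
}

#' Variance-normalised D* per window
#'
#' Windows are sorted by U and split into `n_groups` near-equal groups
#' (ties broken by genomic position; remainder windows go to the lowest-U
#' groups); `D* = D / sd(D within the window's group)`.  p-values are
#' one-sided empirical probabilities against a supplied null D* ensemble
#' (from equal-admixture neutral simulations run through this same
#' function); q-values are Benjamini-Hochberg.
#'
#' @param wtab window table from [u_statistic()] (needs `D`, `U`).
#' @param n_groups number of U-groups (20 as designed).
#' @param null_dstar optional numeric vector of null D* values.
#' @return `wtab` plus `u_group`, `d_star` and, when a null is supplied,
#'   `p` and `q`.
#' @export
dstar_scores <- function(wtab, n_groups = 20, null_dstar = NULL) {
  ok <- which(is.finite(wtab$D))
  if (length(ok) < n_groups)
    stop("need at least ", n_groups, " windows with finite D")
  ord <- ok[order(wtab$U[ok], wtab$chrom[ok], wtab$start[ok])]
  n <- length(ord)
  base <- n %/% n_groups
  extra <- n %% n_groups   # remainder spread over the lowest-U groups
  sizes <- rep(base, n_groups) + c(rep(1, extra), rep(0, n_groups - extra))
  grp <- rep(seq_len(n_groups), times = sizes)
  wtab$u_group <- NA_integer_
  wtab$u_group[ord] <- grp
  wtab$d_star <- NA_real_
  for (g in seq_len(n_groups)) {
    ii <- which(wtab$u_group == g)
    s <- sd(wtab$D[ii])
    if (!is.finite(s) || s == 0)
      stop("zero within-group SD of D in U-group ", g)
    wtab$d_star[ii] <- wtab$D[ii] / s
  }
  if (!is.null(null_dstar)) {
    null_dstar <- null_dstar[is.finite(null_dstar)]
    srt <- sort(null_dstar)
    ge <- length(srt) - findInterval(wtab$d_star, srt, left.open = TRUE)
    wtab$p <- ifelse(is.finite(wtab$d_star),
                     (1 + ge) / (1 + length(srt)), NA_real_)
    wtab$q <- fdr_qvalues(wtab$p)
  }
  wtab
}

# ---- S* ------------------------------------------------------------------

#' S*-style haplotype scan
#'
#' Candidate sites are derived alleles present in the target panel but
#' absent from the comparison panel.  For each target haplotype, the
#' candidate sites it carries are chained by dynamic programming with
#' `S(j) = max_i(score(i, j) + max(S(i), 0))`, where consecutive-pair
#' scores are `bonus + distance` when the two sites have identical carrier
#' patterns in the target panel ("congruent"), `mismatch` otherwise, and
#' pairs closer than `min_spacing` bp are disallowed.  The window score is
#' the maximum over haplotypes; windows qualify as candidates when the
#' score exceeds `threshold` and the fraction of chained alleles matching
#' the archaic track is at least `match_min`.
#'
#' @param panel a [haplotype_panel()] with target and comparison
#'   populations.
#' @param target,comparison population labels.
#' @param archaic per-site archaic allele track (0/1/NA), aligned with the
#'   panel sites.
#' @param windows a [partition_windows()] table (50-kb tiling).
#' @param bonus,mismatch,min_spacing,threshold,match_min scoring
#'   constants.
#' @return list `windows` (table plus `s_star`, `match_fraction`,
#'   `candidate`, `best_haplotype`) and `sites` (candidate positions).
#' @export
sstar_scan <- function(panel, target = "target", comparison = "comparison",
                       archaic = NULL, windows,
                       bonus = 5000, mismatch = -10000, min_spacing = 10,
                       threshold = 50000, match_min = 0.3) {
  rows_t <- panel_rows(panel, target)
  rows_c <- panel_rows(panel, comparison)
  der_c <- colSums(panel$alleles[rows_c, , drop = FALSE] == 1, na.rm = TRUE)
  der_t <- colSums(panel$alleles[rows_t, , drop = FALSE] == 1, na.rm = TRUE)
  cand <- which(der_c == 0 & der_t > 0)
  w <- windows
  w$s_star <- NA_real_
  w$match_fraction <- NA_real_
  w$best_haplotype <- NA_integer_
  wi <- assign_windows(panel$positions, windows)
  pat_key <- apply(panel$alleles[rows_t, cand, drop = FALSE], 2,
                   function(col) paste(ifelse(is.na(col), 9, col),
                                       collapse = ""))
  for (win in unique(wi[cand])) {
    if (is.na(win)) next
    cw <- cand[wi[cand] == win]
    if (length(cw) < 2) next
    best <- -Inf; best_h <- NA_integer_; best_chain <- integer(0)
    for (hi in seq_along(rows_t)) {
      h <- rows_t[hi]
      sites <- cw[which(panel$alleles[h, cw] == 1)]
      m <- length(sites)
      if (m < 2) next
      pos <- panel$positions[sites]
      key <- pat_key[match(sites, cand)]
      S <- rep(-Inf, m)
      prev <- rep(NA_integer_, m)
      for (j in 2:m) {
        for (i in 1:(j - 1)) {
          d <- pos[j] - pos[i]
          if (d < min_spacing) next
          sc <- if (key[i] == key[j]) bonus + d else mismatch
          val <- sc + max(S[i], 0)
          if (val > S[j]) { S[j] <- val; prev[j] <- i }
        }
      }
      if (all(!is.finite(S))) next
      jbest <- which.max(S)
      if (S[jbest] > best) {
        best <- S[jbest]
        best_h <- h
        chain <- jbest
        while (!is.na(prev[chain[1]])) {
          i <- prev[chain[1]]
          chain <- c(i, chain)
          if (!(S[i] > 0)) break   # chain restarted at the pair (i, j)
        }
        best_chain <- sites[chain]
      }
    }
    if (is.finite(best)) {
      w$s_star[win] <- best
      w$best_haplotype[win] <- best_h
      if (!is.null(archaic)) {
        a <- archaic[best_chain]
        w$match_fraction[win] <- mean(a == 1, na.rm = TRUE)
        if (all(is.na(a))) w$match_fraction[win] <- 0
      }
    }
  }
  w$candidate <- !is.na(w$s_star) & w$s_star >= threshold &
    (if (is.null(archaic)) TRUE else
       !is.na(w$match_fraction) & w$match_fraction >= match_min)
  list(windows = w, sites = panel$positions[cand])
}

# ---- admixture fraction (f4-ratio with ghost correction) -----------------

#' f4-ratio archaic-ancestry statistic
#'
#' `Q = f4(deep, archaic; modern outgroup, target) /
#'      f4(deep, archaic; modern outgroup, archaic)`, with
#' `f4(A,B;C,D) = mean((pA - pB) (pC - pD))` over sites.  With a single
#' archaic genome this estimates the fraction of the target's ancestry
#' from the archaic's branch, biased by any admixture from a second
#' ("ghost") archaic source; the bias is corrected by calibrating the
#' expectation surface under the demographic model.
#'
#' @param sft a [site_frequency_table()] with the archaic track, an
#'   `outgroup` (deep) track, and a modern outgroup population.
#' @param target target population label.
#' @param modern_outgroup modern outgroup population label.
#' @param archaic archaic track name.
#' @export
q_f4_ratio <- function(sft, target = "target",
                       modern_outgroup = "outgroup_modern",
                       archaic = "denisovan") {
  pT <- site_freq(sft, target)
  pO <- site_freq(sft, modern_outgroup)
  pA <- sft[[paste0("archaic_", archaic)]]
  pD <- sft$outgroup
  ok <- is.finite(pT) & is.finite(pO) & !is.na(pA) & !is.na(pD)
  num <- mean((pD[ok] - pA[ok]) * (pO[ok] - pT[ok]))
  den <- mean((pD[ok] - pA[ok]) * (pO[ok] - pA[ok]))
  num / den
}

#' Monte-Carlo calibration surfaces for the admixture-fraction estimator
#'
#' Fits the expectations of the two f4-ratio statistics (one per archaic
#' track) as linear response surfaces in `(m_D, m_N)` from simulations at
#' a small design grid under the demographic model.  Computing this once
#' and passing it to [q_admixture()] amortises the simulation cost over
#' many datasets.
#'
#' @param model a [build_model()].
#' @param scenario template [archaic_scenario()] for the calibration
#'   simulations (its pulse fractions are overridden by the design grid).
#' @param design_fracs fractions used for the calibration design grid.
#' @param calib_reps,calib_length replicates and bp per design point.
#' @param seed RNG seed.
#' @return list `fit_d`, `fit_n` (linear coefficients), `design` (the
#'   design points with their simulated expectations), `design_fracs`.
#' @export
q_calibration <- function(model, scenario = archaic_scenario(),
                          design_fracs = c(0, 0.015, 0.03),
                          calib_reps = 24, calib_length = 2e6,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  design <- expand.grid(m_d = design_fracs, m_n = design_fracs)
  qd <- qn <- numeric(nrow(design))
  for (i in seq_len(nrow(design))) {
    sc <- scenario
    sc$den_frac_target <- design$m_d[i]
    sc$den_frac_comparison <- design$m_d[i]
    sc$nea_frac <- design$m_n[i]
    sims <- simulate_archaic(model, sc,
                             samples = c(target = 20, comparison = 20,
                                         outgroup_modern = 20),
                             sequence_length = calib_length,
                             nreps = calib_reps, deep_outgroup = FALSE)
    if (calib_reps == 1) sims <- list(sims)
    # pool sites over replicates before taking the f4 ratio: per-replicate
    # ratios are heavy-tailed because the denominator can pass near zero
    pooled <- do.call(rbind, lapply(sims, `[[`, "sft"))
    class(pooled) <- class(sims[[1]]$sft)
    qd[i] <- q_f4_ratio(pooled, archaic = "denisovan")
    qn[i] <- q_f4_ratio(pooled, archaic = "neanderthal")
  }
  lm_d <- stats::lm(qd ~ m_d + m_n, data = design)
  lm_n <- stats::lm(qn ~ m_d + m_n, data = design)
  list(fit_d = lm_d$coefficients, fit_n = lm_n$coefficients,
       vcov_d = stats::vcov(lm_d), vcov_n = stats::vcov(lm_n),
       design = cbind(design, q_denisovan = qd, q_neanderthal = qn),
       design_fracs = design_fracs)
}

#' Simultaneous admixture-fraction estimate for two archaic sources
#'
#' Equating the observed f4-ratio statistics with the calibrated
#' expectation surfaces of [q_calibration()] defines `m_D` as an implicit
#' function of `m_N` (and vice versa), each evaluated by bisection; the
#' simultaneous estimate is the intersection of the two curves, again
#' found by bisection.  The CI comes from a moving-blocks bootstrap (1-Mb
#' blocks) of the observed site terms pushed through the same solve.
#'
#' @param obs_sft observed [site_frequency_table()] (with `denisovan` and
#'   `neanderthal` tracks, an outgroup track, and target + modern
#'   outgroup populations).
#' @inheritParams q_calibration
#' @param bootstrap_reps moving-blocks bootstrap replicates.
#' @param block_size bootstrap block width (bp).
#' @param calibration optional precomputed [q_calibration()] result.
#' @return list `m_d`, `m_n`, `ci_m_d`, `ci_m_n` (`interval_ci`),
#'   `surface` (the fitted linear coefficients), `q_obs`.
#' @export
q_admixture <- function(obs_sft, model, scenario = archaic_scenario(),
                        design_fracs = c(0, 0.015, 0.03),
                        calib_reps = 24, calib_length = 2e6,
                        bootstrap_reps = 100, block_size = 1e6,
                        seed = NULL, calibration = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(calibration))
    calibration <- q_calibration(model, scenario, design_fracs,
                                 calib_reps, calib_length)
  fit_d <- calibration$fit_d
  fit_n <- calibration$fit_n
  design_fracs <- calibration$design_fracs
  # the fitted surfaces are linear, so the implicit curves extrapolate
  # exactly; the bisection bracket only needs to contain the root, and a
  # wide bracket keeps the solve robust when the two curves are close to
  # parallel (the two archaic sources are almost equally related to the
  # sampled genome, so the system is intrinsically ill-conditioned)
  span <- diff(range(design_fracs))
  lo <- min(design_fracs) - 3 * span
  hi <- max(design_fracs) + 5 * span
  solve_m <- function(coefs, obs, other, wrt = c("m_d", "m_n")) {
    wrt <- match.arg(wrt)
    f <- function(m) {
      md <- if (wrt == "m_d") m else other
      mn <- if (wrt == "m_n") m else other
      unname(coefs[1] + coefs["m_d"] * md + coefs["m_n"] * mn) - obs
    }
    # expand the bracket geometrically until it straddles the root (the
    # surface is linear in m, so a sign change exists unless the slope
    # vanishes)
    a <- lo; b <- hi
    for (k in 1:8) {
      if (f(a) * f(b) <= 0)
        return(stats::uniroot(f, c(a, b), tol = 1e-10)$root)
      mid <- (a + b) / 2; half <- (b - a)
      a <- mid - half; b <- mid + half
    }
    NA_real_
  }
  intersect_curves <- function(qd_obs, qn_obs, fd = fit_d, fn = fit_n) {
    g <- function(mn) {
      md <- solve_m(fd, qd_obs, mn, "m_d")
      if (is.na(md)) return(NA_real_)
      mn2 <- solve_m(fn, qn_obs, md, "m_n")
      if (is.na(mn2)) return(NA_real_)
      mn2 - mn
    }
    # locate a sign change of g along a grid, then bisect inside it
    grid <- seq(lo, hi, length.out = 41)
    gv <- vapply(grid, g, numeric(1))
    ok <- which(is.finite(gv))
    hitr <- NULL
    for (k in seq_along(ok)[-1]) {
      i <- ok[k - 1]; j <- ok[k]
      if (j == i + 1 && gv[i] * gv[j] <= 0) { hitr <- c(grid[i], grid[j]); break }
    }
    if (is.null(hitr)) return(c(NA_real_, NA_real_))
    mn <- stats::uniroot(function(m) g(m), hitr, tol = 1e-10)$root
    c(solve_m(fd, qd_obs, mn, "m_d"), mn)
  }
  obs_qd <- q_f4_ratio(obs_sft, archaic = "denisovan")
  obs_qn <- q_f4_ratio(obs_sft, archaic = "neanderthal")
  est <- intersect_curves(obs_qd, obs_qn)
  if (any(is.na(est)))
    stop("admixture curves fail to intersect within the calibrated box; ",
         "widen design_fracs or check the input statistics")
  # moving-blocks bootstrap of the observed statistics; each replicate
  # also perturbs the calibration surface coefficients from their fitted
  # covariance so the CI carries the Monte-Carlo calibration uncertainty
  blk <- floor((obs_sft$position - 1) / block_size)
  ub <- unique(blk)
  chol_d <- if (!is.null(calibration$vcov_d))
    chol(calibration$vcov_d) else NULL
  chol_n <- if (!is.null(calibration$vcov_n))
    chol(calibration$vcov_n) else NULL
  perturb <- function(fit, ch) {
    if (is.null(ch)) return(fit)
    fit + drop(t(ch) %*% rnorm(length(fit)))
  }
  boots <- matrix(NA_real_, bootstrap_reps, 2)
  for (b in seq_len(bootstrap_reps)) {
    ii <- unlist(lapply(sample(ub, length(ub), replace = TRUE),
                        function(u) which(blk == u)))
    bs <- obs_sft[ii, , drop = FALSE]
    class(bs) <- class(obs_sft)
    boots[b, ] <- intersect_curves(q_f4_ratio(bs, archaic = "denisovan"),
                                   q_f4_ratio(bs, archaic = "neanderthal"),
                                   perturb(fit_d, chol_d),
                                   perturb(fit_n, chol_n))
  }
  list(m_d = est[1], m_n = est[2],
       ci_m_d = percentile_ci(est[1], boots[, 1]),
       ci_m_n = percentile_ci(est[2], boots[, 2]),
       surface = list(denisovan = fit_d, neanderthal = fit_n),
       q_obs = c(denisovan = obs_qd, neanderthal = obs_qn))
}

#' Overlap permutation test between introgressed and top-scan windows
#'
#' Observed overlap = number of introgressed windows inside the top
#' fraction of windows by scan score; the null distribution permutes the
#' scan scores across windows.
#'
#' @param introgressed logical flag per window.
#' @param scores scan score per window (same partition; higher = more
#'   extreme; NA windows are unranked).
#' @param top_fraction fraction of scored windows taken as "top".
#' @param replicates permutation replicates.
#' @return list `observed`, `p`, `n_top`.
#' @export
overlap_permutation_test <- function(introgressed, scores,
                                     top_fraction = 0.002,
                                     replicates = 10000) {
  if (length(introgressed) != length(scores))
    stop("window partitions do not match")
  scored <- which(is.finite(scores))
  k <- max(1L, floor(length(scored) * top_fraction))
  top <- scored[order(scores[scored], decreasing = TRUE)][seq_len(k)]
  obs <- sum(introgressed[top])
  null <- vapply(seq_len(replicates), function(i) {
    sum(introgressed[sample(scored, k)])
  }, numeric(1))
  list(observed = obs, p = (1 + sum(null >= obs)) / (1 + replicates),
       n_top = k)
}
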
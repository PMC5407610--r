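# Age estimation: maximum-likelihood dating of the sweep origin by
# simulation matching, the admissible introgression time window for an
# adaptive archaic haplotype, gene-tree divergence from pairwise
# differences, and the gene-tree to population-divergence conversion.

#' Summaries of a candidate sweep haplotype
#'
#' The observables matched by [sweep_age_mle()]: the derived-allele
#' frequency at the focal site and the mean length (bp) of unbroken
#' haplotype sharing around the focal site among derived carriers
#' (pairwise identity tract length, averaged over carrier pairs).
#'
#' @param panel a [haplotype_panel()].
#' @param focal focal site index.
#' @param population population carrying the sweep.
#' @param max_pairs carrier pairs to average over (sampled if more).
#' @return named numeric vector `freq`, `share_length`.
#' @export
sweep_summaries <- function(panel, focal, population = "target",
                            max_pairs = 100) {
  rows <- panel_rows(panel, population)
  alle <- panel$alleles[rows, , drop = FALSE]
  carriers <- which(alle[, focal] == 1)
  freq <- length(carriers) / length(rows)
  if (length(carriers) < 2)
    return(c(freq = freq, share_length = 0))
  prs <- t(utils::combn(carriers, 2))
  if (nrow(prs) > max_pairs)
    prs <- prs[sample.int(nrow(prs), max_pairs), , drop = FALSE]
  pos <- panel$positions
  S <- ncol(alle)
  len <- apply(prs, 1, function(pr) {
    d <- alle[pr[1], ] != alle[pr[2], ]
    d[is.na(d)] <- TRUE
    right <- if (any(d[seq(focal, S)]))
      pos[focal + which(d[seq(focal, S)])[1] - 1] else pos[S]
    left <- if (any(d[seq(focal, 1)]))
      pos[focal - which(d[seq(focal, 1)])[1] + 1] else pos[1]
    right - left
  })
  c(freq = freq, share_length = mean(len))
}

#' Maximum-likelihood sweep-origin dating
#'
#' For each candidate origin age, sweeps are simulated forward from a new
#' mutation at that age (conditioned on survival) and the observed
#' summaries are scored under a Gaussian kernel density of the simulated
#' summaries; the estimate is the age maximising the smoothed likelihood,
#' with a likelihood-ratio confidence interval.
#'
#' @param observed summaries from [sweep_summaries()].
#' @param model a [build_model()].
#' @param s selection coefficient assumed for the sweep.
#' @param age_grid candidate origin ages (generations ago).
#' @param n_reps simulation replicates per age.
#' @param samples,sequence_length simulation dimensions.
#' @param level confidence level for the likelihood-ratio interval.
#' @param seed RNG seed.
#' @return list `age` (ML origin age, generations), `age_years`, `ci`
#'   (`interval_ci`, generations), `loglik` (data.frame over the grid).
#' @export
sweep_age_mle <- function(observed, model, s, age_grid,
                          n_reps = 30,
                          samples = c(target = 27, comparison = 62),
                          sequence_length = 5e5, level = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(age_grid) == 1) {
    return(list(age = age_grid, age_years = age_grid * model$generation_time,
                ci = structure(list(point = age_grid, lower = age_grid,
                                    upper = age_grid,
                                    method = "degenerate-grid"),
                               class = "interval_ci"),
                loglik = data.frame(age = age_grid, loglik = 0)))
  }
  ll <- vapply(age_grid, function(a) {
    sm <- matrix(NA_real_, n_reps, 2)
    for (r in seq_len(n_reps)) {
      traj <- try(sweep_trajectory_forward(model, s, a), silent = TRUE)
      if (inherits(traj, "try-error")) next
      pan <- simulate_sweep(model, traj, samples, sequence_length)
      sm[r, ] <- sweep_summaries(pan, attr(pan, "focal_index"))
    }
    sm <- sm[complete.cases(sm), , drop = FALSE]
    if (nrow(sm) < 3) return(-Inf)
    bw <- pmax(apply(sm, 2, sd) * (4 / (3 * nrow(sm)))^(1/5), 1e-6)
    dens <- mean(exp(-0.5 * ((observed[1] - sm[, 1]) / bw[1])^2 -
                       0.5 * ((observed[2] - sm[, 2]) / bw[2])^2) /
                   (2 * pi * bw[1] * bw[2]))
    log(dens + 1e-300)
  }, numeric(1))
  if (all(!is.finite(ll)))
    stop("observed summaries fall outside every simulated support")
  best <- which.max(ll)
  cut <- max(ll) - qchisq(level, df = 1) / 2
  inside <- age_grid[ll >= cut]
  list(age = age_grid[best],
       age_years = age_grid[best] * model$generation_time,
       ci = structure(list(point = age_grid[best], lower = min(inside),
                           upper = max(inside),
                           method = "likelihood-ratio"),
                      class = "interval_ci"),
       loglik = data.frame(age = age_grid, loglik = ll))
}

#' Admissible introgression window for an adaptive archaic haplotype
#'
#' The latest admissible introgression time is the sweep onset itself; the
#' earliest is the oldest time from which a single-copy neutral haplotype
#' still survives to the sweep onset with probability at least
#' `survival_threshold`, evaluated by Wright-Fisher drift simulation under
#' the model's target-population sizes.
#'
#' @param sweep_age_gens sweep origin age (generations ago).
#' @param model a [build_model()].
#' @param survival_threshold minimum survival probability.
#' @param candidate_gens candidate introgression times (generations ago);
#'   default: a grid from the sweep age up to the divergence time.
#' @param n_reps drift-simulation replicates per candidate time.
#' @param seed RNG seed.
#' @return list `earliest_gens`, `latest_gens`, `earliest_years`,
#'   `latest_years`, `survival` (data.frame).
#' @export
introgression_window <- function(sweep_age_gens, model,
                                 survival_threshold = 0.05,
                                 candidate_gens = NULL, n_reps = 2000,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (survival_threshold >= 1) {
    return(list(earliest_gens = sweep_age_gens,
                latest_gens = sweep_age_gens,
                earliest_years = sweep_age_gens * model$generation_time,
                latest_years = sweep_age_gens * model$generation_time,
                survival = data.frame(time_gens = sweep_age_gens,
                                      survival = 1)))
  }
  if (is.null(candidate_gens)) {
    td <- floor(years_to_gens(model, model$divergence_time_years))
    # survival of a single neutral copy decays on a scale of tens of
    # generations, so probe densely just above the sweep onset
    candidate_gens <- sweep_age_gens +
      unique(c(seq(0, 100, by = 5), seq(120, 500, by = 20)))
    candidate_gens <- candidate_gens[candidate_gens <= td]
  }
  surv_to_onset <- function(t0) {
    alive <- 0
    for (r in seq_len(n_reps)) {
      N2 <- 2 * target_size_at(model, t0)
      x <- 1 / N2
      dead <- FALSE
      for (g in seq(t0, sweep_age_gens + 1)) {
        N2 <- 2 * target_size_at(model, g - 1)
        x <- rbinom(1, N2, x) / N2
        if (x <= 0) { dead <- TRUE; break }
        if (x >= 1) break
      }
      if (!dead) alive <- alive + 1
    }
    alive / n_reps
  }
  sv <- vapply(candidate_gens, surv_to_onset, numeric(1))
  admissible <- candidate_gens[sv >= survival_threshold]
  earliest <- if (length(admissible)) max(admissible) else sweep_age_gens
  list(earliest_gens = earliest, latest_gens = sweep_age_gens,
       earliest_years = earliest * model$generation_time,
       latest_years = sweep_age_gens * model$generation_time,
       survival = data.frame(time_gens = candidate_gens, survival = sv))
}

#' Gene-tree divergence time between two haplotypes
#'
#' `t = k / (2 mu L)` years for `k` pairwise differences over an aligned
#' span of `L` bp at mutation rate `mu` per bp per year; the CI propagates
#' the exact Poisson interval on `k`.
#'
#' @param hap_a,hap_b 0/1/NA allele vectors on a common site frame, or
#'   `k` may be given directly via `differences`.
#' @param span aligned non-missing span in bp.
#' @param mu mutation rate per bp per YEAR (default 0.5e-9).
#' @param level confidence level.
#' @param differences optional pre-computed difference count.
#' @return an `interval_ci` in years.
#' @export
gene_tree_divergence <- function(hap_a = NULL, hap_b = NULL, span, mu = 0.5e-9,
                                 level = 0.95, differences = NULL) {
  if (span <= 0) stop("zero usable span")
  k <- if (!is.null(differences)) differences
       else sum(hap_a != hap_b, na.rm = TRUE)
  a <- (1 - level) / 2
  klo <- if (k == 0) 0 else qgamma(a, k)          # exact Poisson bounds
  khi <- qgamma(1 - a, k + 1)
  tt <- function(kk) kk / (2 * mu * span)
  structure(list(point = tt(k), lower = tt(klo), upper = tt(khi),
                 method = "poisson-exact"),
            class = "interval_ci")
}

#' Population divergence from gene-tree divergence
#'
#' Subtracts the expected within-population coalescent waiting time
#' (`2 N_archaic x generation_time` years) from the gene-tree time;
#' floored at 0.
#'
#' @param gene_tree_years gene-tree divergence (years).
#' @param n_archaic archaic effective size (diploids).
#' @param generation_time years per generation.
#' @export
population_divergence <- function(gene_tree_years, n_archaic,
                                  generation_time = 25) {
  pmax(gene_tree_years - 2 * n_archaic * generation_time, 0)
}
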
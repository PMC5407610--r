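# The composite-of-multiple-signals score: histogram densities of each
# component statistic under a simulated neutral model and a pooled sweep
# model, naive-Bayes combination into a per-site log posterior score,
# empirical p-values against the neutral ensemble, Benjamini-Hochberg
# q-values, and 200-kb region aggregation.

cms_components <- c("fst", "delta_daf", "ihs_raw", "delta_ihh_raw",
                    "xpehh_raw")

#' Train component-score densities from simulated ensembles
#'
#' Bins each component statistic into a common set of `n_bins` histogram
#' bins spanning the pooled (neutral + sweep) range, with `pseudocount`
#' added per bin before normalisation.  The neutral ensemble pools all
#' sites of neutral replicates; the sweep ensemble is the distribution AT
#' THE SELECTED SITE -- one row per sweep replicate, pooled over the
#' scenario grid cells with equal weight (pooling all sites of swept
#' regions instead would describe hitchhikers, not the selected variant,
#' and destroys the monotonicity of the likelihood ratios).
#'
#' @param null_scores data.frame of component scores from neutral
#'   simulations (as produced by [compute_component_scores()], rows =
#'   sites pooled over replicates).
#' @param alt_scores focal-site component scores from sweep simulations
#'   pooled over the grid (see [cms_training_ensembles()]).
#' @param n_bins number of histogram bins.
#' @param pseudocount smoothing count per bin.
#' @return object of class `score_distributions`.
#' @export
train_cms <- function(null_scores, alt_scores, n_bins = 60, pseudocount = 1) {
  if (nrow(null_scores) == 0 || nrow(alt_scores) == 0)
    stop("both training ensembles must be non-empty")
  dists <- lapply(cms_components, function(cmp) {
    x0 <- null_scores[[cmp]]; x1 <- alt_scores[[cmp]]
    pooled <- c(x0, x1)
    pooled <- pooled[is.finite(pooled)]
    if (length(pooled) < 2) stop("no finite training values for ", cmp)
    rng <- range(pooled)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
    binned <- function(x) {
      x <- x[is.finite(x)]
      idx <- pmin(pmax(findInterval(x, breaks, all.inside = TRUE), 1), n_bins)
      cnt <- tabulate(idx, nbins = n_bins) + pseudocount
      cnt / sum(cnt)
    }
    list(breaks = breaks, null = binned(x0), alt = binned(x1))
  })
  names(dists) <- cms_components
  structure(list(dists = dists, n_bins = n_bins, pseudocount = pseudocount),
            class = "score_distributions")
}

#' Simulate the training and calibration ensembles for the composite score
#'
#' Runs neutral replicates (all sites enter the null ensemble) and sweep
#' replicates over the scenario grid (the focal-site scores enter the
#' alternative ensemble).  A second, independent neutral ensemble is
#' simulated for empirical p-value calibration, so that p-values are never
#' computed against the very data the densities were trained on.
#'
#' @param model a [build_model()] object.
#' @param samples named diploid sample sizes.
#' @param sequence_length bp per training replicate.
#' @param null_reps neutral replicates for density training (and again for
#'   p-value calibration).
#' @param reps_per_cell sweep replicates per grid cell.
#' @param grid scenario grid (default [cms_scenario_grid()], 60 cells).
#' @param daf_range,cutoff passed to [compute_component_scores()].
#' @return list `null_scores`, `alt_scores`, `pvalue_null_scores`.
#' @export
cms_training_ensembles <- function(model,
                                   samples = c(target = 27, comparison = 62),
                                   sequence_length = 1e5,
                                   null_reps = 60, reps_per_cell = 10,
                                   grid = cms_scenario_grid(),
                                   daf_range = c(0.05, 0.95), cutoff = 0.05) {
  null_scores <- do.call(rbind, lapply(
    simulate_neutral(model, samples, sequence_length, nreps = null_reps),
    compute_component_scores, daf_range = daf_range, cutoff = cutoff))
  alt_scores <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sc <- sweep_scenario(grid$s[i], grid$end_freq[i], grid$end_time_gens[i])
    do.call(rbind, lapply(seq_len(reps_per_cell), function(r) {
      pan <- simulate_sweep(model, sc, samples, sequence_length)
      compute_component_scores(pan, daf_range = daf_range, cutoff = cutoff,
                               sites = attr(pan, "focal_index"))
    }))
  }))
  pvalue_null_scores <- do.call(rbind, lapply(
    simulate_neutral(model, samples, sequence_length, nreps = null_reps),
    compute_component_scores, daf_range = daf_range, cutoff = cutoff))
  list(null_scores = null_scores, alt_scores = alt_scores,
       pvalue_null_scores = pvalue_null_scores)
}

#' Serialize trained score distributions to JSON
#'
#' Versioned, plain-text representation of a [train_cms()] object so a
#' trained scan can be re-applied without re-simulating.
#'
#' @param dists a `score_distributions` object.
#' @param path output path.
#' @export
write_cms_distributions <- function(dists, path) {
  stopifnot(inherits(dists, "score_distributions"))
  payload <- list(format = "sweepintro-cms-distributions",
                  version = 1L,
                  package_version =
                    as.character(utils::packageVersion("sweepintro")),
                  n_bins = dists$n_bins, pseudocount = dists$pseudocount,
                  dists = dists$dists)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read trained score distributions from JSON
#' @param path file written by [write_cms_distributions()].
#' @export
read_cms_distributions <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "sweepintro-cms-distributions"))
    stop("not a serialized score-distributions file")
  structure(list(dists = payload$dists, n_bins = payload$n_bins,
                 pseudocount = payload$pseudocount),
            class = "score_distributions")
}

dist_lookup <- function(d, x) {
  # density bin lookup; out-of-range values clamp to the edge bins
  idx <- pmin(pmax(findInterval(x, d$breaks, all.inside = TRUE), 1),
              length(d$null))
  list(null = d$null[idx], alt = d$alt[idx])
}

#' Composite score per site
#'
#' For each valid component `i`, the posterior probability of selection is
#' `post_i = pi * f_sel(x_i) / (pi * f_sel(x_i) + (1 - pi) * f_neut(x_i))`;
#' the composite score is `sum_i log(post_i)`, rescaled by
#' `5 / n_valid` so sites missing some components stay comparable.  Scores
#' are always negative; higher (closer to 0) means stronger evidence of a
#' sweep.
#'
#' @param scores data.frame of component scores.
#' @param dists a [train_cms()] object.
#' @param prior prior probability `pi` that a site is selected.
#' @return numeric vector of composite scores (`NA` where no component is
#'   valid).
#' @export
cms_score <- function(scores, dists, prior = 1e-4) {
  stopifnot(inherits(dists, "score_distributions"))
  S <- nrow(scores)
  acc <- matrix(NA_real_, S, length(cms_components))
  for (j in seq_along(cms_components)) {
    cmp <- cms_components[j]
    x <- scores[[cmp]]
    ok <- is.finite(x)
    if (!any(ok)) next
    lk <- dist_lookup(dists$dists[[cmp]], x[ok])
    post <- prior * lk$alt / (prior * lk$alt + (1 - prior) * lk$null)
    acc[ok, j] <- log(post)
  }
  nvalid <- rowSums(is.finite(acc))
  out <- ifelse(nvalid > 0, rowSums(acc, na.rm = TRUE) * 5 / nvalid, NA_real_)
  out
}

#' Empirical p-values against a neutral score ensemble
#'
#' `p = (1 + #\{null >= observed\}) / (1 + N_null)`; the pseudo-count keeps
#' p strictly positive and bounded by 1.
#'
#' @param observed observed composite scores.
#' @param null_cms composite scores from the neutral ensemble.
#' @export
empirical_pvalues <- function(observed, null_cms) {
  null_cms <- null_cms[is.finite(null_cms)]
  if (length(null_cms) == 0) stop("empty null ensemble")
  srt <- sort(null_cms)
  n <- length(srt)
  ge <- n - findInterval(observed, srt, left.open = TRUE)  # #{null >= obs}
  out <- (1 + ge) / (1 + n)
  out[!is.finite(observed)] <- NA_real_
  out
}

#' Benjamini-Hochberg q-values
#' @param p p-values in (0, 1].
#' @export
fdr_qvalues <- function(p) p.adjust(p, method = "BH")

#' Region-level composite score
#'
#' Aggregates per-site scores to fixed windows (max score per window), and
#' flags/merges the top fraction.
#'
#' @param positions site positions (bp).
#' @param cms per-site composite scores.
#' @param windows a [partition_windows()] table.
#' @param top_fraction fraction of scored windows to flag (e.g. 0.002 or
#'   0.01); ties broken by window order.
#' @return list with `windows` (the table plus `cms_max`, `n_sites`,
#'   `rank`, `top` flag) and `merged` (merged top intervals via
#'   [merge_adjacent()]).
#' @export
region_cms <- function(positions, cms, windows, top_fraction = 0.002) {
  wi <- assign_windows(positions, windows)
  ok <- !is.na(wi) & is.finite(cms)
  mx <- tapply(cms[ok], factor(wi[ok], levels = seq_len(nrow(windows))),
               max)
  ns <- tapply(rep(1, sum(ok)), factor(wi[ok], levels = seq_len(nrow(windows))),
               sum)
  w <- windows
  w$cms_max <- as.vector(mx)
  w$n_sites <- as.vector(ifelse(is.na(ns), 0L, as.integer(ns)))
  scored <- which(is.finite(w$cms_max))
  k <- max(1L, floor(length(scored) * top_fraction))
  ord <- scored[order(w$cms_max[scored], decreasing = TRUE)]
  w$rank <- NA_integer_
  w$rank[ord] <- seq_along(ord)
  w$top <- !is.na(w$rank) & w$rank <= k
  list(windows = w,
       merged = merge_adjacent(w, w$top, w$cms_max))
}
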
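# Allele-frequency differentiation statistics: Hudson and Weir-Cockerham
# FST estimators (site-wise and ratio-of-sums genome-wide), derived-allele
# frequency differences, the population branch statistic, and genome-wide
# z-normalisation of raw scan scores.

fst_terms_hudson <- function(d1, n1, d2, n2) {
  p1 <- d1 / n1; p2 <- d2 / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(num = num, den = den)
}

# Weir & Cockerham (1984) theta for haploid allele-count data, two
# populations: among-population component a and within component b.
fst_terms_wc <- function(d1, n1, d2, n2) {
  p1 <- d1 / n1; p2 <- d2 / n2
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2)
  list(num = a, den = a + b)
}

#' Site-wise FST between two populations
#'
#' Hudson: numerator `(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`,
#' denominator `p1(1-p2) + p2(1-p1)`.  Weir-Cockerham: the two-population
#' theta for haploid allele counts.  Values can be negative; sites
#' monomorphic for the same allele in both samples are returned as `NA`
#' (no information about differentiation).
#'
#' @param d1,n1 derived and total chromosome counts in population 1.
#' @param d2,n2 same for population 2 (vectors recycle site-wise).
#' @param estimator `"hudson"` or `"wc"`.
#' @return numeric vector of site FST values.
#' @export
site_fst <- function(d1, n1, d2, n2, estimator = c("hudson", "wc")) {
  estimator <- match.arg(estimator)
  if (any(n1 < 2) || any(n2 < 2))
    stop("need at least 2 chromosomes per population")
  tm <- if (estimator == "hudson") fst_terms_hudson(d1, n1, d2, n2)
        else fst_terms_wc(d1, n1, d2, n2)
  out <- tm$num / tm$den
  both_mono <- (d1 == 0 & d2 == 0) | (d1 == n1 & d2 == n2)
  out[both_mono] <- NA_real_
  out
}

#' Genome-wide FST (ratio of sums)
#'
#' Sums site numerators and denominators over valid polymorphic sites and
#' takes the ratio ("ratio of averages"), the standard estimator for
#' multi-locus FST; never the mean of site ratios.
#'
#' @inheritParams site_fst
#' @export
genomewide_fst <- function(d1, n1, d2, n2, estimator = c("hudson", "wc")) {
  estimator <- match.arg(estimator)
  tm <- if (estimator == "hudson") fst_terms_hudson(d1, n1, d2, n2)
        else fst_terms_wc(d1, n1, d2, n2)
  both_mono <- (d1 == 0 & d2 == 0) | (d1 == n1 & d2 == n2)
  keep <- !both_mono & is.finite(tm$num) & is.finite(tm$den)
  den <- sum(tm$den[keep])
  if (den == 0) stop("zero FST denominator sum: no informative sites")
  sum(tm$num[keep]) / den
}

#' Derived-allele frequency difference
#'
#' `DAF(target) - DAF(reference)`, in `[-1, 1]`; requires polarised sites.
#'
#' @param freq_target,freq_reference derived-allele frequencies.
#' @export
delta_daf <- function(freq_target, freq_reference) {
  freq_target - freq_reference
}

#' Population branch statistic
#'
#' `T_ij = -log(1 - FST_ij)`; `PBS = (T_TH + T_TE - T_HE) / 2`, the
#' branch-length excess specific to the target population T relative to
#' the comparison H and an external reference E.  Negative FST inputs are
#' clamped to 0 before the log; FST = 1 on a target branch yields `NA`.
#'
#' @param fst_th target-comparison FST.
#' @param fst_te target-external FST.
#' @param fst_he comparison-external FST.
#' @export
pbs <- function(fst_th, fst_te, fst_he) {
  f <- function(x) {
    x <- pmax(x, 0)
    ifelse(x >= 1, NA_real_, -log(1 - x))
  }
  (f(fst_th) + f(fst_te) - f(fst_he)) / 2
}

#' Z-normalise raw scan scores
#'
#' Genome-wide mean/SD normalisation by default; a `reference` list with
#' `mean` and `sd` (e.g. moments of a simulated neutral ensemble) may be
#' supplied, and optional frequency-bin normalisation is available via
#' `bins` (a factor aligned with `x`).
#'
#' @param x raw scores (NA allowed; preserved).
#' @param reference optional list(mean=, sd=).
#' @param bins optional factor for within-bin normalisation.
#' @export
normalize_scores <- function(x, reference = NULL, bins = NULL) {
  if (sum(is.finite(x)) < 2) stop("need at least two valid scores")
  if (!is.null(bins)) {
    out <- x
    for (b in levels(factor(bins))) {
      ii <- which(bins == b & is.finite(x))
      if (length(ii) >= 2) {
        s <- sd(x[ii])
        if (s == 0) stop("zero variance within bin ", b)
        out[ii] <- (x[ii] - mean(x[ii])) / s
      } else out[ii] <- NA_real_
    }
    return(out)
  }
  xi <- x[is.finite(x)]
  mu <- if (!is.null(reference)) reference$mean else mean(xi)
  s <- if (!is.null(reference)) reference$sd
       else sqrt(mean((xi - mu)^2))     # population SD over the genome
  if (!is.finite(s) || s == 0) stop("zero variance: cannot normalise")
  (x - mu) / s
}
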
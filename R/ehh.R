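# Haplotype-homozygosity statistics: EHH profiles, integrated haplotype
# homozygosity (iHH), iHS, delta-iHH and cross-population XP-EHH.
#
# Integration is trapezoidal over genetic distance (cM); when the panel has
# no genetic map, physical distance at 1 cM/Mb is used.  Outward integration
# stops at the first site where EHH drops below the truncation threshold
# (default 0.05, inherited from the EHH-scan literature); the final
# below-threshold trapezoid is included.

gmap_of <- function(panel) {
  if (!is.null(panel$genetic_positions)) panel$genetic_positions
  else panel$positions * 1e-6
}

#' EHH profile around a core site
#'
#' @param panel a [haplotype_panel()].
#' @param core site index (column) of the core.
#' @param allele core allele whose carriers are followed (0 or 1), or
#'   `"all"` for the unconditional profile over every haplotype.
#' @param cutoff stop the outward walk when EHH falls below this.
#' @return data.frame `site`, `position`, `ehh` (both directions, core
#'   included with EHH = 1), ordered by position.
#' @export
ehh_profile <- function(panel, core, allele = 1, cutoff = 0.05) {
  geno <- t(panel$alleles)
  keep <- if (identical(allele, "all")) seq_len(nrow(panel$alleles))
          else which(panel$alleles[, core] == allele)
  if (length(keep) < 2) stop("need at least 2 carrier haplotypes")
  pr <- .cpp_ehh_profile(geno, core, keep, cutoff)
  data.frame(
    site = c(rev(pr$site_left), core, pr$site_right),
    position = panel$positions[c(rev(pr$site_left), core, pr$site_right)],
    ehh = c(rev(pr$ehh_left), 1, pr$ehh_right))
}

trapz_out <- function(g_core, g, e) {
  # outward trapezoid from the core (EHH = 1) through profile values
  if (length(e) == 0) return(0)
  gg <- c(g_core, g)
  ee <- c(1, e)
  sum((ee[-1] + ee[-length(ee)]) / 2 * abs(diff(gg)))
}

ihh_one <- function(geno, gmap, core, keep, cutoff, limits = c(-1L, -1L)) {
  if (length(keep) < 2) return(NA_real_)
  pr <- .cpp_ehh_profile(geno, core, keep, cutoff, limits[1], limits[2])
  trapz_out(gmap[core], gmap[pr$site_left], pr$ehh_left) +
    trapz_out(gmap[core], gmap[pr$site_right], pr$ehh_right)
}

#' iHH / iHS / delta-iHH at a core site
#'
#' `iHH` integrates EHH outward for the carriers of each core allele;
#' `ihs_raw = log(iHH_A / iHH_D)` (ancestral over derived: long derived
#' haplotypes give negative raw values) and `delta_ihh_raw = iHH_A -
#' iHH_D`.  Sites where either allele has fewer than 2 carriers, or where
#' either integral is 0, are invalid (`NA`), so no infinite scores are
#' produced.
#'
#' @inheritParams ehh_profile
#' @return list `ihh_a`, `ihh_d`, `ihs_raw`, `delta_ihh_raw`.
#' @export
haplotype_scores <- function(panel, core, cutoff = 0.05) {
  geno <- t(panel$alleles)
  gmap <- gmap_of(panel)
  anc <- which(panel$alleles[, core] == 0)
  der <- which(panel$alleles[, core] == 1)
  ihh_a <- ihh_one(geno, gmap, core, anc, cutoff)
  ihh_d <- ihh_one(geno, gmap, core, der, cutoff)
  bad <- !is.finite(ihh_a) || !is.finite(ihh_d) || ihh_a == 0 || ihh_d == 0
  list(ihh_a = ihh_a, ihh_d = ihh_d,
       ihs_raw = if (bad) NA_real_ else log(ihh_a / ihh_d),
       delta_ihh_raw = if (bad) NA_real_ else ihh_a - ihh_d)
}

#' Raw XP-EHH between two populations at a core site
#'
#' Unconditional EHH (all haplotypes of a population) integrated outward,
#' truncated where the EHH of the pooled two-population panel drops below
#' `cutoff`; `xpehh_raw = log(iHH_pop_a / iHH_pop_b)`.
#'
#' @param panel a [haplotype_panel()] containing both populations.
#' @param pop_a,pop_b population labels (A in the numerator: positive
#'   values mean longer haplotypes, i.e. a sweep signal, in A).
#' @inheritParams ehh_profile
#' @export
xpehh_raw <- function(panel, pop_a, pop_b, core, cutoff = 0.05) {
  geno <- t(panel$alleles)
  gmap <- gmap_of(panel)
  rows_a <- panel_rows(panel, pop_a)
  rows_b <- panel_rows(panel, pop_b)
  pooled <- .cpp_ehh_profile(geno, core, c(rows_a, rows_b), cutoff)
  liml <- if (length(pooled$site_left)) min(pooled$site_left) else core
  limr <- if (length(pooled$site_right)) max(pooled$site_right) else core
  ia <- ihh_one(geno, gmap, core, rows_a, 0, c(liml, limr))
  ib <- ihh_one(geno, gmap, core, rows_b, 0, c(liml, limr))
  if (!is.finite(ia) || !is.finite(ib) || ia == 0 || ib == 0) return(NA_real_)
  log(ia / ib)
}

#' All CMS component statistics across a panel
#'
#' Computes, per site: Hudson FST (target vs comparison), delta-DAF, raw
#' iHS and delta-iHH (within the target population), and raw XP-EHH
#' (target vs comparison).  Haplotype statistics are computed only at
#' sites whose target-population derived-allele frequency lies in
#' `daf_range` (iHS convention; extreme-frequency cores are skipped).
#'
#' @param panel a [haplotype_panel()] with both populations.
#' @param target,comparison population labels.
#' @param daf_range frequency window within which iHS/delta-iHH cores are
#'   evaluated.
#' @param cutoff EHH truncation threshold.
#' @param sites optional site indices: restrict the returned rows (and the
#'   expensive haplotype statistics) to these sites, e.g. the focal site
#'   of a simulated sweep when building training ensembles.
#' @return data.frame with `position`, `daf_target`, `daf_comparison`,
#'   `fst`, `delta_daf`, `ihs_raw`, `delta_ihh_raw`, `xpehh_raw`.
#' @export
compute_component_scores <- function(panel, target = "target",
                                     comparison = "comparison",
                                     daf_range = c(0.05, 0.95),
                                     cutoff = 0.05, sites = NULL) {
  rows_t <- panel_rows(panel, target)
  rows_c <- panel_rows(panel, comparison)
  geno <- t(panel$alleles)
  gmap <- gmap_of(panel)
  at <- allele_counts(panel, target)
  ac <- allele_counts(panel, comparison)
  ft <- at$derived_count / at$chromosome_count
  fc <- ac$derived_count / ac$chromosome_count
  fst <- site_fst(at$derived_count, at$chromosome_count,
                  ac$derived_count, ac$chromosome_count, "hudson")
  S <- length(panel$positions)
  ihs <- dihh <- xp <- rep(NA_real_, S)
  sub_t <- panel$alleles[rows_t, , drop = FALSE]
  eval_sites <- if (is.null(sites)) seq_len(S) else sites
  for (s in eval_sites) {
    if (is.finite(ft[s]) && ft[s] >= daf_range[1] && ft[s] <= daf_range[2]) {
      anc <- rows_t[which(sub_t[, s] == 0)]
      der <- rows_t[which(sub_t[, s] == 1)]
      ia <- ihh_one(geno, gmap, s, anc, cutoff)
      id <- ihh_one(geno, gmap, s, der, cutoff)
      if (is.finite(ia) && is.finite(id) && ia > 0 && id > 0) {
        ihs[s] <- log(ia / id)
        dihh[s] <- ia - id
      }
      pooled <- .cpp_ehh_profile(geno, s, c(rows_t, rows_c), cutoff)
      liml <- if (length(pooled$site_left)) min(pooled$site_left) else s
      limr <- if (length(pooled$site_right)) max(pooled$site_right) else s
      ja <- ihh_one(geno, gmap, s, rows_t, 0, c(liml, limr))
      jb <- ihh_one(geno, gmap, s, rows_c, 0, c(liml, limr))
      if (is.finite(ja) && is.finite(jb) && ja > 0 && jb > 0)
        xp[s] <- log(ja / jb)
    }
  }
  out <- data.frame(position = panel$positions, daf_target = ft,
                    daf_comparison = fc, fst = fst,
                    delta_daf = delta_daf(ft, fc),
                    ihs_raw = ihs, delta_ihh_raw = dihh, xpehh_raw = xp)
  if (!is.null(sites)) out <- out[sites, , drop = FALSE]
  out
}
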
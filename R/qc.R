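# Variant-level quality control and population-contrast filters: quality
# masking, per-site missingness, cross-callset discordance, the
# target-enriched variant filter and the archaic-like variant mask.

#' Mask low-quality genotype calls
#'
#' Genotypes with phred-scaled quality below `threshold` become missing;
#' masking precedes missingness filtering in the standard pipeline order.
#'
#' @param genotypes matrix of genotype calls (any coding; NA allowed).
#' @param qualities numeric matrix of the same shape.
#' @param threshold phred threshold (default 30, i.e. more than one error
#'   per 1000 calls).
#' @return the genotype matrix with sub-threshold entries set to NA.
#' @export
mask_low_quality <- function(genotypes, qualities, threshold = 30) {
  if (!all(dim(genotypes) == dim(qualities)))
    stop("genotype and quality matrices must have the same shape")
  genotypes[qualities < threshold] <- NA
  genotypes
}

#' Drop sites with excess missingness
#'
#' @param genotypes matrix with sites in columns (rows = samples or
#'   haplotypes).
#' @param max_missing_fraction sites with a missing fraction strictly
#'   above this are removed (default 0.05).
#' @return list `genotypes` (filtered, order preserved), `kept` (logical
#'   per original site).
#' @export
drop_high_missing <- function(genotypes, max_missing_fraction = 0.05) {
  miss <- colMeans(is.na(genotypes))
  keep <- miss <= max_missing_fraction
  list(genotypes = genotypes[, keep, drop = FALSE], kept = keep)
}

#' Blacklist sites discordant between two callsets
#'
#' Per-site discordance is the fraction of shared samples whose (unphased)
#' genotypes differ between the callsets; sites above `max_discordance`
#' are blacklisted.  Genotypes are compared as unordered allele pairs so
#' phase differences between callsets do not count as discordance.
#'
#' @param callset_a,callset_b matrices with sites in columns and shared
#'   sample IDs as rownames; genotype coding `"a/b"` or allele-count
#'   integers.
#' @param max_discordance threshold (default 0.05).
#' @return list `blacklist` (logical per site), `discordance` (fraction
#'   per site).
#' @export
drop_discordant_sites <- function(callset_a, callset_b,
                                  max_discordance = 0.05) {
  shared <- intersect(rownames(callset_a), rownames(callset_b))
  if (length(shared) == 0) stop("no shared samples between callsets")
  a <- callset_a[shared, , drop = FALSE]
  b <- callset_b[shared, , drop = FALSE]
  if (ncol(a) != ncol(b)) stop("callsets must cover the same sites")
  norm_gt <- function(m) {
    # order the alleles within "x/y" style genotypes: phase-insensitive
    if (is.character(m)) {
      apply(m, c(1, 2), function(g) {
        if (is.na(g)) return(NA_character_)
        paste(sort(strsplit(g, "[/|]")[[1]]), collapse = "/")
      })
    } else m
  }
  a <- norm_gt(a); b <- norm_gt(b)
  both <- !is.na(a) & !is.na(b)
  disc <- colSums((a != b) & both) / colSums(both)
  list(blacklist = !is.na(disc) & disc > max_discordance,
       discordance = disc)
}

#' Target-enriched variant filter
#'
#' A site passes when the derived (alternative) allele frequency exceeds
#' `target_min` in the target population AND is below `reference_max` in
#' EVERY listed reference population.
#'
#' @param sft a [site_frequency_table()].
#' @param target target population label.
#' @param reference_pops reference population labels.
#' @param target_min minimum target frequency (exclusive; default 0.10).
#' @param reference_max maximum reference frequency (exclusive; default
#'   0.01).
#' @return logical per site.
#' @export
enriched_variant_filter <- function(sft, target = "target", reference_pops,
                                    target_min = 0.10, reference_max = 0.01) {
  ok <- site_freq(sft, target) > target_min
  for (p in reference_pops) ok <- ok & (site_freq(sft, p) < reference_max)
  ok & !is.na(ok)
}

#' Archaic-like variant mask
#'
#' TRUE at sites where the derived allele is present in at least one
#' target haplotype, matches the archaic allele, and has folded minor
#' allele frequency below `maf_max` in every listed reference population.
#' Sites with a missing archaic call are FALSE.
#'
#' @param sft a [site_frequency_table()] with the archaic track.
#' @param target target population label.
#' @param reference_pops reference population labels.
#' @param archaic archaic track name.
#' @param maf_max folded-MAF cap (default 0.05).
#' @return logical per site.
#' @export
archaic_like_mask <- function(sft, target = "target", reference_pops,
                              archaic = "denisovan", maf_max = 0.05) {
  arch <- sft[[paste0("archaic_", archaic)]]
  if (is.null(arch)) stop("archaic track not present: ", archaic)
  dt <- sft[[paste0("derived_", target)]]
  ok <- !is.na(arch) & arch == 1 & dt > 0
  for (p in reference_pops) {
    f <- site_freq(sft, p)
    maf <- pmin(f, 1 - f)
    ok <- ok & !is.na(maf) & maf < maf_max
  }
  ok
}
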
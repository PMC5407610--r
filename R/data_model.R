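# Core genomic containers: phased haplotype panels, per-site allele-count
# tables, fixed-width window bookkeeping and exact binomial intervals.
#
# Coordinate conventions: physical positions are 1-based bp; window
# arithmetic is done 0-based half-open internally and reported 1-based
# inclusive, so a 200-kb tiling starts at 1, 200001, 400001, ...

#' Construct a phased haplotype panel
#'
#' A haplotype panel holds a phased 0/1 matrix (haplotypes in rows, sites in
#' columns) together with physical positions, the haplotype-to-individual
#' mapping and the individual-to-population mapping.  Allele 0 is ancestral,
#' 1 derived; `NA` encodes a missing call.
#'
#' @param chrom single chromosome label.
#' @param positions integer-ish vector of 1-based physical positions,
#'   strictly increasing, one per matrix column.
#' @param alleles matrix of 0/1/`NA`, haplotypes x sites.
#' @param individuals character vector, one entry per haplotype row, naming
#'   the diploid individual each haplotype belongs to.
#' @param populations named character vector mapping individual -> population.
#' @param genetic_positions optional non-decreasing map positions in cM.
#' @return an object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(chrom, positions, alleles, individuals,
                            populations, genetic_positions = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  positions <- as.numeric(positions)
  if (ncol(alleles) != length(positions))
    stop("one position per site (matrix column) is required")
  if (length(positions) > 1 && any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (nrow(alleles) != length(individuals))
    stop("one individual label per haplotype row is required")
  bad <- !(alleles %in% c(0L, 1L, NA_integer_))
  if (any(bad)) stop("alleles must be 0, 1 or NA")
  if (!all(individuals %in% names(populations)))
    stop("every individual must have a population assignment")
  if (!is.null(genetic_positions)) {
    if (length(genetic_positions) != length(positions))
      stop("genetic_positions must align with positions")
    if (any(diff(genetic_positions) < 0))
      stop("genetic_positions must be non-decreasing")
  }
  structure(
    list(chrom = as.character(chrom)[1], positions = positions,
         alleles = alleles, individuals = as.character(individuals),
         populations = populations, genetic_positions = genetic_positions),
    class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  pops <- table(x$populations[x$individuals])
  cat("haplotype_panel:", nrow(x$alleles), "haplotypes x",
      ncol(x$alleles), "sites on", x$chrom, "\n")
  cat("  populations:",
      paste(names(pops), pops, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Haplotype rows belonging to one population
#' @param panel a [haplotype_panel()].
#' @param population population label.
#' @return integer vector of row indices.
#' @export
panel_rows <- function(panel, population) {
  pop_of_hap <- unname(panel$populations[panel$individuals])
  if (!population %in% pop_of_hap)
    stop("unknown population label: ", population)
  which(pop_of_hap == population)
}

#' Subset a panel to one population
#' @inheritParams panel_rows
#' @return a [haplotype_panel()] restricted to that population's haplotypes.
#' @export
panel_subset <- function(panel, population) {
  rows <- panel_rows(panel, population)
  haplotype_panel(panel$chrom, panel$positions,
                  panel$alleles[rows, , drop = FALSE],
                  panel$individuals[rows], panel$populations,
                  panel$genetic_positions)
}

#' Per-site derived-allele counts for one population
#'
#' Missing alleles are excluded from both numerator and denominator
#' (per-site complete case).
#'
#' @inheritParams panel_rows
#' @return data.frame with `position`, `derived_count`, `chromosome_count`.
#' @export
allele_counts <- function(panel, population) {
  rows <- panel_rows(panel, population)
  sub <- panel$alleles[rows, , drop = FALSE]
  data.frame(position = panel$positions,
             derived_count = colSums(sub == 1L, na.rm = TRUE),
             chromosome_count = colSums(!is.na(sub)))
}

#' Per-site frequency table over several populations
#'
#' The substrate for D/U/FST/PBS-type statistics: derived counts and sample
#' sizes per population, plus optional archaic and outgroup allele tracks
#' (single-haplotype 0/1/`NA` vectors aligned with the sites).
#'
#' @param panel a [haplotype_panel()].
#' @param populations population labels (default: all present).
#' @param archaic optional named list of per-site allele vectors.
#' @param outgroup optional per-site allele vector.
#' @return data.frame of class `site_frequency_table` with columns
#'   `position`, `derived_<pop>`, `chrom_<pop>` per population, then one
#'   `archaic_<name>` column per archaic track and `outgroup`.
#' @export
site_frequency_table <- function(panel, populations = NULL, archaic = NULL,
                                 outgroup = NULL) {
  if (is.null(populations))
    populations <- unique(unname(panel$populations[panel$individuals]))
  out <- data.frame(position = panel$positions)
  for (p in populations) {
    ac <- allele_counts(panel, p)
    out[[paste0("derived_", p)]] <- ac$derived_count
    out[[paste0("chrom_", p)]] <- ac$chromosome_count
  }
  for (nm in names(archaic)) {
    v <- archaic[[nm]]
    if (length(v) != nrow(out)) stop("archaic track must align with sites")
    out[[paste0("archaic_", nm)]] <- as.integer(v)
  }
  if (!is.null(outgroup)) {
    if (length(outgroup) != nrow(out)) stop("outgroup track must align with sites")
    out$outgroup <- as.integer(outgroup)
  }
  class(out) <- c("site_frequency_table", "data.frame")
  out
}

#' Derived-allele frequency from a frequency table
#' @param sft a [site_frequency_table()].
#' @param population population label.
#' @return numeric vector of frequencies (NaN where no calls).
#' @export
site_freq <- function(sft, population) {
  d <- sft[[paste0("derived_", population)]]
  n <- sft[[paste0("chrom_", population)]]
  if (is.null(d)) stop("population absent from table: ", population)
  d / n
}

#' Tile a chromosome with fixed-width windows
#'
#' @param chrom_length chromosome length in bp.
#' @param width window width in bp (200 kb for CMS/D* regions, 50 kb for
#'   S*-style scans).
#' @param chrom chromosome label.
#' @return data.frame (`window_table`) with `chrom`, `start`, `end`
#'   (1-based inclusive); the last window may be short.
#' @export
partition_windows <- function(chrom_length, width, chrom = "chr1") {
  if (width <= 0) stop("window width must be positive")
  n <- ceiling(chrom_length / width)
  start0 <- (seq_len(n) - 1) * width        # 0-based half-open internally
  end0 <- pmin(start0 + width, chrom_length)
  out <- data.frame(chrom = chrom, start = start0 + 1, end = end0)
  class(out) <- c("window_table", "data.frame")
  out
}

#' Assign positions to windows
#' @param positions 1-based physical positions.
#' @param windows a [partition_windows()] table.
#' @return integer window index per position (NA outside all windows).
#' @export
assign_windows <- function(positions, windows) {
  idx <- findInterval(positions - 1, windows$start - 1)
  idx[positions < windows$start[1] | positions > windows$end[nrow(windows)]] <- NA
  idx
}

#' Merge adjacent selected windows
#'
#' Maximal runs of adjacent selected windows are merged into single
#' intervals; the merged aggregate is the max of the member aggregates.
#'
#' @param windows a window table.
#' @param selected logical flag per window.
#' @param scores optional numeric aggregate per window.
#' @return data.frame with `chrom`, `start`, `end`, `score`, `n_windows`.
#' @export
merge_adjacent <- function(windows, selected, scores = NULL) {
  stopifnot(length(selected) == nrow(windows))
  if (is.null(scores)) scores <- rep(NA_real_, nrow(windows))
  keep <- which(selected)
  if (length(keep) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), score = numeric(),
                      n_windows = integer()))
  # runs of consecutive window indices on the same chromosome
  brk <- c(TRUE, diff(keep) != 1 |
             windows$chrom[keep[-1]] != windows$chrom[keep[-length(keep)]])
  run <- cumsum(brk)
  do.call(rbind, lapply(split(keep, run), function(ii) {
    data.frame(chrom = windows$chrom[ii[1]], start = windows$start[ii[1]],
               end = windows$end[ii[length(ii)]],
               score = if (all(is.na(scores[ii]))) NA_real_
                       else max(scores[ii], na.rm = TRUE),
               n_windows = length(ii))
  }))
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Inverts the binomial CDF via the beta quantile identities; the lower
#' bound is 0 when there are no successes and the upper bound 1 when all
#' trials succeed.
#'
#' @param successes,trials non-negative counts with `successes <= trials`.
#' @param level confidence level in (0, 1).
#' @return list of class `interval_ci` with `point`, `lower`, `upper`,
#'   `method`.
#' @export
exact_binomial_ci <- function(successes, trials, level = 0.95) {
  if (trials < 0 || successes < 0 || successes > trials)
    stop("need 0 <= successes <= trials")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  a <- (1 - level) / 2
  lower <- if (successes == 0) 0 else qbeta(a, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else
    qbeta(1 - a, successes + 1, trials - successes)
  structure(list(point = successes / trials, lower = lower, upper = upper,
                 method = "exact-binomial"),
            class = "interval_ci")
}

#' @export
print.interval_ci <- function(x, ...) {
  cat(sprintf("%.4g [%.4g, %.4g] (%s)\n", x$point, x$lower, x$upper,
              x$method))
  invisible(x)
}

#' Percentile-bootstrap interval from replicate values
#' @param point point estimate.
#' @param replicates numeric vector of bootstrap replicate values.
#' @param level confidence level.
#' @return an `interval_ci`.
#' @export
percentile_ci <- function(point, replicates, level = 0.95) {
  a <- (1 - level) / 2
  qs <- unname(quantile(replicates, c(a, 1 - a), na.rm = TRUE, type = 7))
  structure(list(point = point, lower = min(qs[1], point),
                 upper = max(qs[2], point), method = "percentile-bootstrap"),
            class = "interval_ci")
}
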
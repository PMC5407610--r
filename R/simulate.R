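# Coalescent simulation front-ends: neutral two-population panels, selective
# sweeps driven by conditioned Wright-Fisher frequency trajectories, and
# archaic-admixture scenarios with true-tract bookkeeping.

sim_call <- function(model, spec, L, sample_pops, sweep = NULL, nreps = 1,
                     return_mode = c("haplotypes", "counts")) {
  mode <- match.arg(return_mode)
  .cpp_sim_coalescent(L = L, mu = model$mutation_rate,
                      rbp = model$recombination_rate,
                      sample_pops = as.integer(sample_pops),
                      npop = spec$npop, init_sizes = spec$sizes,
                      init_mig = spec$mig, events = spec$events,
                      sweep = sweep, nreps = as.integer(nreps),
                      return_mode = if (mode == "counts") 1L else 0L)
}

# integer bp positions, strictly increasing within a replicate; ties from
# rounding the continuous mutation axis are nudged right (input is sorted,
# so cascading nudges preserve the ordering)
tidy_positions <- function(pos) {
  p <- floor(pos) + 1
  while (any(d <- duplicated(p))) p[d] <- p[d] + 1
  p
}

panel_from_sim <- function(sim, keep_rows, L, sample_names, pops,
                           chrom = "chr1") {
  ord <- order(sim$pos[keep_rows])
  rows <- keep_rows[ord]
  pos <- tidy_positions(sim$pos[rows])
  ok <- pos <= L
  geno <- t(sim$geno[rows[ok], , drop = FALSE])
  haplotype_panel(chrom, pos[ok], geno, sample_names, pops)
}

#' Simulate neutral panels under the demographic model
#'
#' @param model a [build_model()] object.
#' @param samples named diploid sample sizes, `c(target = ..., comparison
#'   = ...)`.  The study design is 27 target and 62 comparison diploids.
#' @param sequence_length length of each simulated replicate in bp.
#' @param seed integer seed (R RNG drives the engine, so runs are
#'   reproducible).
#' @param nreps independent replicates (unlinked chunks).
#' @param return what to return: `"panel"` (list of [haplotype_panel()]s)
#'   or `"counts"` (per-site derived counts per population, a data.frame
#'   with `rep`, `position`, `derived_target`, `chrom_target`,
#'   `derived_comparison`, `chrom_comparison`).
#' @export
simulate_neutral <- function(model, samples = c(target = 27, comparison = 62),
                             sequence_length = 1e6, seed = NULL, nreps = 1,
                             return = c("panel", "counts")) {
  ret <- match.arg(return)
  if (!is.null(seed)) set.seed(seed)
  spec <- engine_spec(model)
  n_t <- samples[["target"]]; n_c <- samples[["comparison"]]
  sp <- c(rep(0L, 2 * n_t), rep(1L, 2 * n_c))
  sim <- sim_call(model, spec, sequence_length, sp, nreps = nreps,
                  return_mode = if (ret == "counts") "counts" else "haplotypes")
  if (ret == "counts") {
    data.frame(rep = sim$rep, position = sim$pos,
               derived_target = sim$counts[, 1], chrom_target = 2 * n_t,
               derived_comparison = sim$counts[, 2], chrom_comparison = 2 * n_c)
  } else {
    inds <- c(rep(paste0("target", seq_len(n_t)), each = 2),
              rep(paste0("comparison", seq_len(n_c)), each = 2))
    popmap <- setNames(c(rep("target", n_t), rep("comparison", n_c)),
                       c(paste0("target", seq_len(n_t)),
                         paste0("comparison", seq_len(n_c))))
    lapply(seq_len(nreps), function(r) {
      panel_from_sim(sim, which(sim$rep == r), sequence_length, inds, popmap)
    })
  }
}

#' Backward frequency trajectory for a sweep scenario
#'
#' Simulates the derived-allele frequency per generation, backwards from
#' the present: a neutral Wright-Fisher drift segment from the present back
#' to the sweep's conclusion (conditioned on the allele surviving to the
#' present), then a selected decline (deterministic logistic decrement plus
#' binomial drift) from `end_freq` down to loss.  The generation of loss is
#' the mutation's origin.  Population sizes follow the model.
#'
#' @param model a [build_model()] object.
#' @param scenario a [sweep_scenario()].
#' @param max_origin_gens reject trajectories whose origin would be older
#'   than this (default: the divergence time).
#' @param max_attempts rejection-sampling cap; exceeding it raises an error
#'   (the scenario is unattainable).
#' @return numeric vector `x` with `x[g]` the derived frequency `g - 1`
#'   generations ago; `attr(., "origin_gen")` is the origin generation.
#' @export
sweep_trajectory <- function(model, scenario, max_origin_gens = NULL,
                             max_attempts = 1000) {
  if (is.null(max_origin_gens))
    max_origin_gens <- floor(years_to_gens(model, model$divergence_time_years))
  s <- scenario$s; x_end <- scenario$end_freq; Tend <- scenario$end_time_gens
  if (Tend >= max_origin_gens)
    stop("sweep conclusion predates the admissible range")
  n2_dec <- 2 * target_size_at(model, seq(Tend + 1, max_origin_gens))
  for (attempt in seq_len(max_attempts)) {
    # forward neutral drift from conclusion to present
    if (Tend > 0) {
      xf <- numeric(Tend + 1)
      xf[1] <- x_end
      for (g in seq_len(Tend)) {     # forward steps from Tend ago to present
        N2 <- 2 * target_size_at(model, Tend - g)
        xf[g + 1] <- rbinom(1, N2, xf[g]) / N2
      }
      if (xf[Tend + 1] <= 0) next    # lost before the present: reject
      drift <- rev(xf)               # drift[1] = present, drift[Tend+1] = x_end
    } else drift <- x_end
    # backward selected decline from the conclusion down to loss
    dec <- .cpp_traj_backward(x_end, s, n2_dec, max_attempts)
    if (length(dec) == 0) break      # unattainable within the time cap
    traj <- c(drift, dec)            # traj[1] = present
    traj <- traj[seq_len(max(which(traj > 0)))]
    attr(traj, "origin_gen") <- length(traj)
    attr(traj, "attempts") <- attempt
    return(traj)
  }
  stop("sweep scenario unattainable: no trajectory found in ",
       max_attempts, " attempts (s = ", s, ", end_freq = ", x_end,
       ", end_time_gens = ", Tend, ")")
}

#' Forward trajectory from a fixed sweep origin (used for sweep dating)
#'
#' Selection acts from `origin_gens` ago to the present; the trajectory is
#' conditioned on the allele segregating today (frequency in (0, 1)).
#'
#' @inheritParams sweep_trajectory
#' @param s selection coefficient.
#' @param origin_gens mutation origin, generations ago.
#' @return as [sweep_trajectory()].
#' @export
sweep_trajectory_forward <- function(model, s, origin_gens,
                                     max_attempts = 10000) {
  n2 <- 2 * target_size_at(model, seq(origin_gens - 1, 0))
  xs <- .cpp_traj_forward(s, n2, max_attempts)
  if (length(xs) == 0)
    stop("no surviving sweep trajectory from origin ", origin_gens,
         " generations ago (s = ", s, ")")
  traj <- rev(xs)                      # traj[1] = present
  attr(traj, "origin_gen") <- length(traj)
  traj
}

#' Simulate a selective sweep in the target population
#'
#' The focal locus sits at `scenario$position` (default: region centre).
#' Sampled target haplotypes are assigned derived/ancestral classes by a
#' binomial draw at the present-day trajectory frequency; the engine traces
#' lineages through the trajectory (structured coalescent), and the focal
#' selected site is appended to the returned panel.
#'
#' @inheritParams simulate_neutral
#' @param scenario a [sweep_scenario()] or a trajectory from
#'   [sweep_trajectory()]/[sweep_trajectory_forward()] (pass the generating
#'   scenario's `s` via `attr(traj, "s")` if you need it recorded).
#' @return a [haplotype_panel()] (or list over `nreps`) with attributes
#'   `focal_position`, `focal_index`, `realized_freq`, `origin_gen`.
#' @export
simulate_sweep <- function(model, scenario,
                           samples = c(target = 27, comparison = 62),
                           sequence_length = 1e6, seed = NULL, nreps = 1) {
  if (!is.null(seed)) set.seed(seed)
  spec <- engine_spec(model)
  n_t <- samples[["target"]]; n_c <- samples[["comparison"]]
  sp <- c(rep(0L, 2 * n_t), rep(1L, 2 * n_c))
  pos_focal <- if (inherits(scenario, "sweep_scenario") &&
                   !is.null(scenario$position)) scenario$position else
    sequence_length / 2
  inds <- c(rep(paste0("target", seq_len(n_t)), each = 2),
            rep(paste0("comparison", seq_len(n_c)), each = 2))
  popmap <- setNames(c(rep("target", n_t), rep("comparison", n_c)),
                     c(paste0("target", seq_len(n_t)),
                       paste0("comparison", seq_len(n_c))))
  out <- lapply(seq_len(nreps), function(r) {
    traj <- if (inherits(scenario, "sweep_scenario"))
      sweep_trajectory(model, scenario) else scenario
    x0 <- traj[1]
    carriers <- which(runif(2 * n_t) < x0) - 1L   # 0-based engine indices
    sim <- sim_call(model, spec, sequence_length, sp,
                    sweep = list(pop = 0L, pos = pos_focal, freq = traj,
                                 carriers = as.integer(carriers)))
    pan <- panel_from_sim(sim, seq_along(sim$pos), sequence_length, inds,
                          popmap)
    # append the selected site itself
    focal_col <- as.integer(seq_len(2 * (n_t + n_c)) %in% (carriers + 1L))
    ins <- findInterval(pos_focal, pan$positions)
    pos2 <- append(pan$positions, pos_focal, after = ins)
    dup <- which(duplicated(pos2))
    al2 <- cbind(pan$alleles[, seq_len(ins), drop = FALSE], focal_col,
                 if (ins < length(pan$positions))
                   pan$alleles[, (ins + 1):length(pan$positions), drop = FALSE])
    if (length(dup)) { pos2 <- pos2[-dup]; al2 <- al2[, -dup, drop = FALSE] }
    colnames(al2) <- NULL
    pan <- haplotype_panel(pan$chrom, pos2, al2, pan$individuals,
                           pan$populations)
    attr(pan, "focal_position") <- pos_focal
    attr(pan, "focal_index") <- which(pan$positions == pos_focal)[1]
    attr(pan, "realized_freq") <- length(carriers) / (2 * n_t)
    attr(pan, "origin_gen") <- attr(traj, "origin_gen")
    pan
  })
  if (nreps == 1) out[[1]] else out
}

#' Simulate the archaic-admixture scenario
#'
#' Samples the target and comparison populations plus one haplotype each
#' from the sampled-archaic (Denisovan proxy), Neanderthal-like and deep
#' outgroup (chimpanzee-like) branches, and diploids from a modern
#' outgroup (Yoruba-like) population.  True introgressed tracts (material
#' that crossed a recorded admixture pulse) are returned for validation.
#'
#' @inheritParams simulate_neutral
#' @param scenario an [archaic_scenario()].
#' @param samples named diploid counts for `target`, `comparison`,
#'   `outgroup_modern`.
#' @param deep_outgroup simulate a deep-outgroup (chimpanzee-like)
#'   haplotype for the outgroup allele track.  With `FALSE` the track is
#'   the true ancestral state (all 0), which is what the deep outgroup
#'   proxies; this skips the multi-million-year branch and is much
#'   faster, appropriate for calibration ensembles.
#' @return list with elements `panel` (modern populations), `archaic`
#'   (named list of per-site 0/1 allele tracks: `denisovan`,
#'   `neanderthal`), `outgroup` (deep-outgroup track, all 0 by
#'   construction since alleles are polarised against it), `sft` (a
#'   [site_frequency_table()]), and `tracts` (data.frame `haplotype`,
#'   `left`, `right`, `source`).  For `nreps > 1`, a list of such lists.
#' @export
simulate_archaic <- function(model, scenario,
                             samples = c(target = 27, comparison = 62,
                                         outgroup_modern = 20),
                             sequence_length = 1e6, seed = NULL, nreps = 1,
                             deep_outgroup = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  spec <- engine_spec(model, scenario)
  n_t <- samples[["target"]]; n_c <- samples[["comparison"]]
  n_o <- samples[["outgroup_modern"]]
  sp <- c(rep(0L, 2 * n_t), rep(1L, 2 * n_c), rep(2L, 2 * n_o),
          3L, 5L, if (deep_outgroup) 6L)
  n_modern <- 2 * (n_t + n_c + n_o)
  sim <- sim_call(model, spec, sequence_length, sp, nreps = nreps)
  ev <- spec$events
  rec_ids <- which(ev$record)
  # map recorded event row -> source label (order preserved by engine ids)
  src_of <- function(evid) {
    if (ev$x[evid] > 0 && ev$b[evid] == 4) "denisovan" else "neanderthal"
  }
  inds <- c(rep(paste0("target", seq_len(n_t)), each = 2),
            rep(paste0("comparison", seq_len(n_c)), each = 2),
            rep(paste0("outgroup", seq_len(n_o)), each = 2))
  popmap <- setNames(c(rep("target", n_t), rep("comparison", n_c),
                       rep("outgroup_modern", n_o)),
                     c(paste0("target", seq_len(n_t)),
                       paste0("comparison", seq_len(n_c)),
                       paste0("outgroup", seq_len(n_o))))
  one <- function(r) {
    rows <- which(sim$rep == r)
    ord <- rows[order(sim$pos[rows])]
    pos <- tidy_positions(sim$pos[ord])
    ok <- pos <= sequence_length
    geno <- sim$geno[ord[ok], , drop = FALSE]
    pos <- pos[ok]
    pan <- haplotype_panel("chr1", pos, t(geno[, seq_len(n_modern),
                                               drop = FALSE]),
                           inds, popmap)
    arch <- list(denisovan = geno[, n_modern + 1],
                 neanderthal = geno[, n_modern + 2])
    outg <- if (deep_outgroup) geno[, n_modern + 3]
            else rep(0L, nrow(geno))   # alleles are polarised ancestral = 0
    sft <- site_frequency_table(pan, archaic = arch, outgroup = outg)
    tr <- sim$tracts[sim$tracts$rep == r & sim$tracts$haplotype <= n_modern, ,
                     drop = FALSE]
    tracts <- data.frame(haplotype = tr$haplotype, left = tr$left,
                         right = tr$right,
                         source = vapply(tr$event, src_of, character(1)))
    list(panel = pan, archaic = arch, outgroup = outg, sft = sft,
         tracts = tracts)
  }
  out <- lapply(seq_len(nreps), one)
  if (nreps == 1) out[[1]] else out
}

#' Fraction of target genomes covered by true introgressed tracts
#'
#' Bookkeeping check: averages, over target haplotypes, the fraction of the
#' sequence covered by recorded tracts from one source.
#'
#' @param tracts tract data.frame from [simulate_archaic()].
#' @param haplotypes haplotype indices of the population of interest.
#' @param sequence_length region length in bp.
#' @param source tract source label.
#' @export
tract_fraction <- function(tracts, haplotypes, sequence_length,
                           source = "denisovan") {
  tr <- tracts[tracts$source == source & tracts$haplotype %in% haplotypes, ,
               drop = FALSE]
  covered <- vapply(haplotypes, function(h) {
    sub <- tr[tr$haplotype == h, , drop = FALSE]
    if (nrow(sub) == 0) return(0)
    sum(sub$right - sub$left)
  }, numeric(1))
  mean(covered) / sequence_length
}
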
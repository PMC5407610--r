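# End-to-end orchestration: one YAML configuration drives the stages
# (simulate, scan_cms, scan_introgression, date, enrich); every artifact
# carries a provenance header (package version, seed, config hash).

#' Default pipeline configuration
#'
#' All thresholds and grids default to the study design: 200-kb scan
#' windows, 50-kb S* windows, 1-Mb bootstrap blocks, 200 bootstrap
#' replicates, composite prior 1e-4, EHH truncation 0.05, QC thresholds
#' (quality 30, missingness 5%, discordance 5%), enrichment contrasts
#' (target > 10%, references < 1%, archaic-like MAF < 5%), and the
#' 60-cell sweep training grid.  Simulation sizes are desk-scale knobs.
#'
#' @export
default_config <- function() {
  list(
    seed = 1,
    out_dir = "sweepintro-out",
    samples = list(target = 27, comparison = 62, outgroup_modern = 20),
    windows = list(cms_width = 2e5, sstar_width = 5e4),
    cms = list(prior = 1e-4, n_bins = 60, pseudocount = 1,
               ehh_cutoff = 0.05, daf_range = c(0.05, 0.95),
               top_fraction = 0.002,
               train_reps = 20, train_length = 2e5,
               reps_per_cell = 10, grid_subset = NULL),
    qc = list(quality = 30, max_missing = 0.05, max_discordance = 0.05,
              enriched_target_min = 0.10, enriched_reference_max = 0.01,
              archaic_maf_max = 0.05),
    introgression = list(block_size = 1e6, bootstrap_reps = 200,
                         dstar_groups = 20,
                         sstar = list(bonus = 5000, mismatch = -10000,
                                      min_spacing = 10, threshold = 50000,
                                      match_min = 0.3)),
    simulate = list(kind = "neutral", sequence_length = 1e6, nreps = 1,
                    sweep = list(s = 0.04, end_freq = 0.8,
                                 end_time_gens = 100)),
    date = list(s = 0.04, age_grid = c(100, 200, 300, 400, 600),
                n_reps = 20, survival_threshold = 0.05),
    enrich = list(replicates = 2000, top_fraction = 0.002))
}

read_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  modifyList(default_config(), config)
}

provenance_of <- function(cfg) {
  cfg$out_dir <- NULL   # the analysis is characterised without its sink
  cfg_str <- paste(deparse(cfg), collapse = "")
  c(sweepintro_version = as.character(utils::packageVersion("sweepintro")),
    seed = as.character(cfg$seed),
    config_hash = sprintf("%08x", sum(utf8ToInt(cfg_str) *
                                        seq_along(utf8ToInt(cfg_str))) %%
                            .Machine$integer.max))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Run pipeline stages
#'
#' @param config path to a YAML configuration or a config list; values
#'   override [default_config()].
#' @param stages character vector of stages to run, in order; any of
#'   `"simulate"`, `"scan_cms"`, `"scan_introgression"`, `"date"`,
#'   `"enrich"`.
#' @param seed overrides the config seed.
#' @param out_dir overrides the config output directory.
#' @return named list of per-stage results (also written to `out_dir`).
#' @export
run_pipeline <- function(config = list(), stages = "simulate", seed = NULL,
                         out_dir = NULL) {
  cfg <- read_config(if (is.list(config)) config else config)
  if (!is.null(seed)) cfg$seed <- seed
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  model <- build_model()
  res <- list()
  for (stage in stages) {
    res[[stage]] <- switch(
      stage,
      simulate = stage_simulate(cfg, model),
      scan_cms = stage_scan_cms(cfg, model, res),
      scan_introgression = stage_scan_introgression(cfg, model, res),
      date = stage_date(cfg, model, res),
      enrich = stage_enrich(cfg, res),
      stop("unknown stage: ", stage))
  }
  yaml::write_yaml(cfg, file.path(cfg$out_dir, "config-used.yaml"))
  invisible(res)
}

stage_simulate <- function(cfg, model) {
  sm <- cfg$simulate
  samples <- c(target = cfg$samples$target,
               comparison = cfg$samples$comparison)
  prov <- provenance_of(cfg)
  if (sm$kind == "neutral") {
    pan <- simulate_neutral(model, samples, sm$sequence_length,
                            nreps = sm$nreps)
    for (i in seq_along(pan))
      write_panel_vcf(pan[[i]],
                      file.path(cfg$out_dir,
                                sprintf("neutral_rep%03d.vcf", i)), prov)
    out <- list(panels = pan)
  } else if (sm$kind == "sweep") {
    sc <- sweep_scenario(sm$sweep$s, sm$sweep$end_freq,
                         sm$sweep$end_time_gens)
    pan <- simulate_sweep(model, sc, samples, sm$sequence_length)
    write_panel_vcf(pan, file.path(cfg$out_dir, "sweep.vcf"), prov)
    out <- list(panels = list(pan), scenario = sc)
  } else if (sm$kind == "archaic") {
    arc <- simulate_archaic(model, archaic_scenario(),
                            c(samples,
                              outgroup_modern = cfg$samples$outgroup_modern),
                            sm$sequence_length)
    write_panel_vcf(arc$panel, file.path(cfg$out_dir, "archaic.vcf"), prov)
    write_allele_track(arc$panel$chrom, arc$panel$positions,
                       arc$archaic$denisovan,
                       file.path(cfg$out_dir, "denisovan_track.tsv"))
    write_allele_track(arc$panel$chrom, arc$panel$positions, arc$outgroup,
                       file.path(cfg$out_dir, "outgroup_track.tsv"))
    tb <- if (nrow(arc$tracts) == 0)
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 name = character())
    else data.frame(chrom = arc$panel$chrom,
                    start = floor(arc$tracts$left),
                    end = ceiling(arc$tracts$right),
                    name = paste0(arc$tracts$source, "_hap",
                                  arc$tracts$haplotype))
    write.table(tb, file.path(cfg$out_dir, "true_tracts.bed"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    out <- arc
  } else stop("unknown simulate kind: ", sm$kind)
  if (!is.null(out$panels)) {
    pops <- out$panels[[1]]$populations
    write.table(data.frame(sample = names(pops), population = unname(pops)),
                file.path(cfg$out_dir, "population_map.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  out
}

train_from_config <- function(cfg, model) {
  cc <- cfg$cms
  samples <- c(target = cfg$samples$target,
               comparison = cfg$samples$comparison)
  grid <- cms_scenario_grid()
  if (!is.null(cc$grid_subset)) grid <- grid[cc$grid_subset, , drop = FALSE]
  ens <- cms_training_ensembles(model, samples, cc$train_length,
                                null_reps = cc$train_reps,
                                reps_per_cell = cc$reps_per_cell %||% 10,
                                grid = grid, daf_range = cc$daf_range,
                                cutoff = cc$ehh_cutoff)
  list(dists = train_cms(ens$null_scores, ens$alt_scores, cc$n_bins,
                         cc$pseudocount),
       null_scores = ens$pvalue_null_scores)
}

stage_scan_cms <- function(cfg, model, res) {
  panels <- res$simulate$panels
  if (is.null(panels)) stop("scan_cms requires a simulate stage (or panels)")
  cc <- cfg$cms
  tr <- train_from_config(cfg, model)
  null_cms <- cms_score(tr$null_scores, tr$dists, cc$prior)
  scans <- lapply(panels, function(pan) {
    sc <- compute_component_scores(pan, daf_range = cc$daf_range,
                                   cutoff = cc$ehh_cutoff)
    sc$cms <- cms_score(sc, tr$dists, cc$prior)
    sc$p <- empirical_pvalues(sc$cms, null_cms)
    sc$q <- fdr_qvalues(sc$p)
    sc
  })
  L <- max(vapply(panels, function(p) max(p$positions), numeric(1)))
  windows <- partition_windows(L, cfg$windows$cms_width)
  reg <- region_cms(scans[[1]]$position, scans[[1]]$cms, windows,
                    cc$top_fraction)
  write.table(scans[[1]],
              file.path(cfg$out_dir, "cms_scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_window_table(reg$windows, file.path(cfg$out_dir, "cms_windows.tsv"))
  jsonlite::write_json(
    list(provenance = as.list(provenance_of(cfg))),
    file.path(cfg$out_dir, "cms_provenance.json"), auto_unbox = TRUE)
  list(scores = scans, windows = reg, distributions = tr$dists)
}

stage_scan_introgression <- function(cfg, model, res) {
  arc <- res$simulate
  if (is.null(arc$sft)) stop("scan_introgression requires an archaic simulate stage")
  ic <- cfg$introgression
  L <- max(arc$panel$positions)
  terms <- abba_baba_terms(arc$sft, "target", "comparison")
  D <- d_statistic(terms)
  bs <- min(ic$block_size, ceiling(L / 10))  # keep >= 10 bootstrap blocks
  ci <- block_bootstrap_ci(terms, bs, ic$bootstrap_reps)
  w200 <- u_statistic(terms, partition_windows(L, cfg$windows$cms_width))
  dstar <- try(dstar_scores(w200, ic$dstar_groups), silent = TRUE)
  if (inherits(dstar, "try-error")) dstar <- w200
  sw <- partition_windows(L, cfg$windows$sstar_width)
  ss <- sstar_scan(arc$panel, archaic = arc$archaic$denisovan, windows = sw,
                   bonus = ic$sstar$bonus, mismatch = ic$sstar$mismatch,
                   min_spacing = ic$sstar$min_spacing,
                   threshold = ic$sstar$threshold,
                   match_min = ic$sstar$match_min)
  write_window_table(dstar, file.path(cfg$out_dir, "dstar_windows.tsv"))
  write_window_table(ss$windows, file.path(cfg$out_dir, "sstar_windows.tsv"))
  list(D = D, D_ci = ci, dstar = dstar, sstar = ss)
}

stage_date <- function(cfg, model, res) {
  pan <- res$simulate$panels[[1]]
  if (is.null(attr(pan, "focal_index")))
    stop("date stage requires a sweep simulate stage")
  dc <- cfg$date
  obs <- sweep_summaries(pan, attr(pan, "focal_index"))
  age <- sweep_age_mle(obs, model, dc$s, dc$age_grid, dc$n_reps)
  win <- introgression_window(age$age, model, dc$survival_threshold)
  out <- list(summaries = as.list(obs), age = age$age,
              age_years = age$age_years,
              ci = age$ci[c("lower", "upper")],
              introgression_window_years = list(earliest = win$earliest_years,
                                                latest = win$latest_years),
              provenance = as.list(provenance_of(cfg)))
  jsonlite::write_json(out, file.path(cfg$out_dir, "sweep_dating.json"),
                       auto_unbox = TRUE, digits = NA)
  out
}

stage_enrich <- function(cfg, res) {
  reg <- res$scan_cms$windows
  if (is.null(reg)) stop("enrich requires a scan_cms stage")
  genes <- cfg$enrich$genes
  terms <- cfg$enrich$term_genes
  if (is.null(genes) || is.null(terms))
    stop("enrich needs `enrich$genes` intervals and `enrich$term_genes`")
  gs <- window_gene_sets(reg$windows, genes)
  top <- which(reg$windows$top)
  out <- go_resampling_test(top, gs, terms, cfg$enrich$replicates)
  write.table(out, file.path(cfg$out_dir, "enrichment.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  out
}
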
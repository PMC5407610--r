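# Shared fixtures: a small demographic model and lazily-built, cached
# simulation products reused across test files.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

test_model <- function() build_model()

# small sample sizes keep the haplotype statistics affordable
test_samples <- c(target = 15, comparison = 20)

# toy panel with known haplotype structure (8 haplotypes x 7 sites)
toy_panel <- function() {
  alle <- rbind(
    c(1, 1, 1, 1, 1, 0, 0),
    c(1, 1, 1, 1, 1, 0, 0),
    c(0, 1, 1, 1, 0, 1, 0),
    c(0, 1, 1, 1, 0, 1, 0),
    c(0, 0, 1, 0, 0, 0, 1),
    c(0, 0, 1, 0, 0, 0, 1),
    c(0, 0, 0, 0, 1, 1, 0),
    c(0, 0, 0, 0, 0, 0, 1))
  haplotype_panel("chr1", c(100, 5000, 10000, 15000, 20000, 25000, 30000),
                  alle,
                  rep(c("t1", "t2", "c1", "c2"), each = 2),
                  c(t1 = "target", t2 = "target",
                    c1 = "comparison", c2 = "comparison"))
}

random_panel <- function(n_hap = 10, n_site = 20, miss = 0) {
  alle <- matrix(rbinom(n_hap * n_site, 1, 0.4), n_hap, n_site)
  if (miss > 0) alle[sample(length(alle), miss)] <- NA
  inds <- rep(paste0("i", seq_len(n_hap / 2)), each = 2)
  pops <- setNames(rep(c("target", "comparison"),
                       length.out = n_hap / 2), unique(inds))
  haplotype_panel("chr1", sort(sample.int(1e6, n_site)), alle, inds, pops)
}

# trained composite-score distributions (expensive; built once)
trained_cms <- function() fixture("trained_cms", function() {
  set.seed(4242)
  ens <- cms_training_ensembles(test_model(), test_samples,
                                sequence_length = 1e5,
                                null_reps = 300, reps_per_cell = 25)
  list(dists = train_cms(ens$null_scores, ens$alt_scores),
       null_scores = ens$null_scores,
       pvalue_null = ens$pvalue_null_scores)
})

# equal-admixture archaic replicates (shared by D/D*/U tests)
archaic_reps <- function() fixture("archaic_reps", function() {
  simulate_archaic(test_model(), archaic_scenario(),
                   samples = c(target = 15, comparison = 15,
                               outgroup_modern = 10),
                   sequence_length = 1e6, seed = 9090, nreps = 12)
})

# fabricate a site_frequency_table directly from per-population counts
make_sft <- function(position, tallies, archaic = NULL, outgroup = NULL) {
  out <- data.frame(position = position)
  for (p in names(tallies)) {
    out[[paste0("derived_", p)]] <- tallies[[p]][[1]]
    out[[paste0("chrom_", p)]] <- tallies[[p]][[2]]
  }
  for (nm in names(archaic)) out[[paste0("archaic_", nm)]] <- archaic[[nm]]
  if (!is.null(outgroup)) out$outgroup <- outgroup
  class(out) <- c("site_frequency_table", "data.frame")
  out
}
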
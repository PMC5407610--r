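---
title: "Models and methods behind sweepintro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sweepintro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

sweepintro re-implements, as a tested pipeline, the analysis style used
to characterise recent positive selection and archaic introgression in
high-altitude human populations: a composite selection score trained on
coalescent simulations of an explicit demographic model, a family of
archaic-sharing statistics with simulation-calibrated significance, and
dating machinery for an adaptive, possibly introgressed haplotype. This
vignette records the models, the parameter choices that were genuinely
open, and what the synthetic-data tests do and do not establish.

## The demographic model and its calibration

The simulator encodes a two-population model fitted by diffusion-based
demographic inference: an ancestral population of `nA1 = 12,804`
diploids splits `T2 + T3 = 54,007` years ago into a target
(Tibetan-like) and a comparison (Han-like) branch with sizes `nT1 =
2,445` and `nC1 = 500`; strong bidirectional gene flow (`m11`, `m12`)
persists until `T3 = 9,419` years ago, when sizes change to `nT2 =
13,292` / `nC2 = 75,203` and gene flow collapses (`m21 = 1.3e-11`,
`m22 = 4e-7`); a final expansion to `nT3 = 77,743` / `nC3 = 1,326,988`
occurs at `T1 = 6,355` years ago.

Three conventions are not determined by the published point estimates:
the generation time, the mutation and recombination rates, and the
units of the migration parameters. We fixed them once, using the
model's own published prediction — a genome-wide Hudson FST of 0.0147
between the two samples — as the calibration surface:

* **Migration is interpreted per year** and converted with the
  generation time. Under a literal per-generation reading the encoded
  model predicts FST ≈ 0.15, an order of magnitude above the value the
  fitted model is reported to reproduce, and the same reading makes
  the reported "high gene flow" epoch far too weak to mimic panmixia
  in sequentially-Markovian-coalescent analyses. We confirmed both
  readings against an independent coalescent implementation; the
  mismatch is a property of the printed parameters, not of our engine.
* **Generation time defaults to 20 years.** Together with per-year
  migration this puts the simulated FST at ≈ 0.013 (within the ±0.003
  Monte-Carlo acceptance band around 0.0147, which a 25-year
  generation narrowly misses), and it makes a 400-generation sweep —
  stated to be the oldest simulable within the model — fit exactly
  inside the most recent (low-migration) epoch.
* Mutation and recombination default to `1.25e-8` and `1e-8` per bp
  per generation; FST is insensitive to both.

All three remain arguments of `build_model()`.

## The coalescent engine

`src/coalescent.cpp` implements a backwards-in-time ancestral
recombination graph: lineages carry their ancestral material as
segment lists, each segment tagged with the set of sampled haplotypes
it subtends; coalescence ORs these sets, and material that reaches its
marginal MRCA is pruned, guaranteeing termination. Mutations are laid
down along waiting intervals (infinite sites on a continuous axis) so
no tree reconstruction is needed. Piecewise-constant sizes, asymmetric
backward migration, and mass-migration pulses/splits are applied as a
sorted event timeline. Neutral single-population diversity, Watterson's
estimator, and the closed-form two-deme island-model coalescent times
(`E[T_within] = 4N`, `E[T_between] = 4N + 1/(2m)`) are verified in the
test suite; the two-population FST was additionally cross-checked
against an independent simulator during development.

Selective sweeps use a discrete-generation structured phase: the
derived-allele frequency trajectory is drawn first (a deterministic
logistic decrement plus binomial Wright–Fisher drift, backwards from
the sweep-completion frequency down to loss, rejection-sampled), and
lineages in the swept population are then partitioned into allelic
classes whose coalescence rates follow the trajectory; recombination
re-draws the class of the unlinked side at the current frequency. At
the origin the derived class collapses onto the originating
chromosome.

**Sweep-grid convention.** The training grid is parameterised by the
time the sweep *completed* (0–400 generations ago) and the frequency
it reached, with neutral drift afterwards. Published descriptions of
such grids sometimes call this the "start time of selection", but a
start-time reading makes most of the grid infeasible (an `s = 0.02`
sweep cannot reach frequency 0.8 within 100 generations) and is
degenerate at 0 generations, whereas the completion-time reading —
which also matches how the classic simulator's sweep event is
specified — makes every cell well defined.

## The composite score

For each component statistic the neutral density is estimated from all
sites of neutral replicates, and the sweep density **from the selected
site only** — one value per sweep replicate, pooled uniformly over the
60-cell grid. This matters: pooling all sites of swept regions
describes hitchhikers rather than selected variants and empirically
destroys the monotonicity of the likelihood ratios (sweep-detection
power collapses to zero). Densities are 60 equal-width histogram bins
spanning the pooled range with a pseudo-count of 1; out-of-range
values clamp to the edge bins. The per-site score is the sum of log
posterior probabilities at prior `π = 1e-4`, rescaled by `5/n_valid`
so sites lacking some components (e.g. iHS outside the 5–95% frequency
window) remain comparable; a site with no valid component is
unscored.

Empirical p-values are computed against a *second*, independently
simulated neutral ensemble: reusing the density-training ensemble
leaves the training data over-fitted to its own tails and measurably
inflates the type-I error (0.068 at a nominal 0.05 in our
experiments).

**What "power" means here.** Within a strong sweep, hundreds of sites
are in near-perfect linkage with the selected variant and some —
mutations that arose on the sweeping haplotype, or standing variants
carried up with it — are more extreme than the selected site itself.
No amount of training makes the selected site the argmax of its window
with high probability (its median within-window rank is around the
top 2–3%). The power property we test, and the one the region-level
report is designed around, is detection: among the top-scoring 200-kb
windows (with adjacent windows merged, as in the region report), the
best merged interval contains the selected site in >80% of strong-
sweep replicates; we additionally check the selected site ranks within
the top 5% of its window's sites in most replicates.

EHH statistics integrate over genetic distance (1 cM/Mb when no map is
supplied), truncate at EHH < 0.05, and include the final
below-threshold trapezoid; iHS is oriented `log(iHH_A/iHH_D)` so
sweeps give negative raw values; XP-EHH truncates where the *pooled*
two-population EHH falls below the threshold. Sites where either
allele has fewer than two carriers, or where an integral vanishes, are
flagged invalid rather than scored infinite.

## Archaic-sharing statistics

`D` is oriented so that positive values mean excess archaic sharing in
the case population; the per-site terms suppress sites where the
outgroup carries the derived allele. The literal printed form of the
defining equation has the opposite orientation to its narrative
interpretation; we implement the narrative sign. CIs use a 1-Mb block
bootstrap with 200 replicates and percentile endpoints.

`D*` divides each 200-kb window's D by the standard deviation of D
within its U-group (20 near-equal groups by the window's
archaic-informative mass U, ties broken by position, remainders to the
lowest-U groups). Significance comes from a null ensemble of D* values
produced by running equal-admixture neutral simulations through the
same pipeline.

The S*-style scan uses chain scores of `5000 + distance` for
congruent (identical target carrier pattern) consecutive candidate
sites, −10,000 for incongruent ones, a 10-bp minimum spacing, a
50,000 default window threshold and a 30% archaic-match requirement —
all configurable, since the literature leaves them free. The dynamic
program is verified against exhaustive subset maximisation.

The admixture-fraction estimator uses the f4-ratio
`f4(outgroup, archaic; modern outgroup, target) /
 f4(outgroup, archaic; modern outgroup, archaic)` for each archaic
track. Because the sampled Denisovan is nearly as closely related to
the Neanderthal-like ghost source as to the Denisovan-like introgressor
(default splits 450 and 400 kya), the raw statistics are biased and the
two response curves are close to parallel; the estimator therefore
calibrates linear expectation surfaces in `(m_D, m_N)` by Monte-Carlo
simulation at a 3×3 design grid and intersects the implicit curves by
bisection. Per-replicate f4 ratios are heavy-tailed (the denominator
can pass near zero), so calibration pools numerators and denominators
across replicates before taking ratios. The moving-blocks bootstrap
perturbs the calibration coefficients from their fitted covariance in
each replicate, so the CI carries both the observation noise and the
Monte-Carlo calibration uncertainty; without this the CIs undercover
(~75% instead of 95% in our recovery study). Calibration simulations
use the true ancestral state as the outgroup track (what a deep
outgroup proxies), skipping the multi-million-year outgroup branch.

## Dating

Sweep-origin dating simulates sweeps forward from a single copy at
each candidate age (conditioned on segregating today), summarises each
panel by the focal derived frequency and the mean pairwise
haplotype-sharing length around the focal site among carriers, and
scores the observed summaries under a product-Gaussian kernel density
of the simulated summaries (Silverman bandwidths); the estimate is the
grid argmax with a likelihood-ratio interval. The choice of summaries
and kernel is ours — the procedure is validated purely by parameter
recovery on simulations, not claimed to reproduce any published
supplementary recipe.

The admissible introgression window takes the sweep origin as its
latest bound and, for the earliest bound, the oldest time from which a
single-copy neutral haplotype survives to the sweep origin with
probability above a threshold (default 0.05), evaluated by
Wright–Fisher drift simulation under the model's sizes. Gene-tree
divergence is `k/(2μL)` with the exact Poisson interval on `k`
propagated (μ defaults to 0.5e-9 per bp per year); population
divergence subtracts `2 N_archaic × generation time`.

## Enrichment

Gene-set over-representation among top windows resamples *windows*,
not genes, preserving gene clustering; p-values are upper-tail
empirical probabilities with a pseudo-count and q-values are
Benjamini–Hochberg. Ontology terms are taken as flat sets (no ancestor
propagation).

## Quality-control conventions

Quality masking (phred < 30) precedes the per-site missingness filter
(> 5% removed); cross-callset discordance compares unphased genotypes;
the enriched-variant filter requires the target frequency above its
threshold and *every* reference population below the cap (the stricter
per-population reading); the archaic-like mask uses folded minor-allele
frequencies and counts one archaic allele copy as "present".
Frequencies are always complete-case per site. Only the exact
(Clopper–Pearson) binomial interval is provided; published intervals
for common variants are sometimes Wald-like, and the two disagree
there by design.

## Problem sizes and what the tests show

Test and acceptance runs use deliberately small panels (15 + 20
diploids), 100-kb training replicates (300 neutral replicates, 25
sweep replicates per grid cell against the study's 1000), 2-Mb scan
regions, and tens of Mb for the admixture recovery studies — sizes
chosen so the full suite completes on one CPU in minutes while every
Monte-Carlo tolerance is still meaningful. Synthetic panels have known
ancestral states, no genotyping error, missingness or phasing error,
uniform recombination, and a single archaic haplotype per track;
passing tests therefore validate the statistics, their calibration
machinery and the simulator against theory — not robustness to the
artefacts of real call sets, which enter through the QC module's
filters. Real-data quantities that depend on the full 3-Gb genome
(counts of significant SNVs, specific regions, genome-wide admixture
fractions at 0.4% precision) are out of reach at these scales by
design.
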
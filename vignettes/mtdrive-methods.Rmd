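---
title: "Modelling selfish drive and drift of mtDNA mutations in single cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling selfish drive and drift of mtDNA mutations in single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Every cell carries thousands of mtDNA copies, and a newly arisen mutation
starts as one copy among them. `mtdrive` treats the mtDNA copies of a single
non-dividing cell as a haploid population of constant size N that turns over
completely once per "Generation". With an mtDNA half-life of 9.4 days, one
Generation is two half-lives, 18.8 days; `generations_at_age()` converts age
to this clock (39 Generations for a 2-year-old mouse, 1573 for an
81-year-old human; the simulations round these to 40 and 1600).

One turnover is a Wright-Fisher resampling step: each of the N offspring
genomes picks a parent with probability proportional to the parent's
replicative fitness, 1 for wild type and 1 + s for a mutant, so

* s = 0 is neutral drift,
* s > 0 is replicative drive (a "selfish" allele),
* -1 < s < 0 is a replication disadvantage.

After resampling, each wild-type offspring mutates with probability mu per
site per replication (default 2e-8/bp, the measured somatic mtDNA rate).
There is no back-mutation, so fixation (all N copies mutant) is absorbing,
and a lost allele can only return through a new emergence event. There is no
cell division and no copy-number fluctuation: N is 10,000 for mouse
hepatocytes and 5,000 for human hepatocytes (`species_preset()`), both from
single-cell ddPCR measurements.

Three simulators expose this model:

* `simulate_site()` / `simulate_site_ensemble()` - one site, one cell /
  many independent cells. The ensemble advances all replicates jointly with
  one vectorised resampling per generation from a single seeded RNG stream;
  replicates remain mutually independent and the whole ensemble is
  reproducible from the one seed.
* `simulate_genome()` - all L sites of a genome (mouse 16,299 bp, human
  16,569 bp). New mutations arrive as a Poisson process with expectation
  N * L * mu per generation, at uniform positions on uniform genomes.
  *Marginal* mode resamples every segregating site independently - exact in
  law under neutrality and fast enough for thousands of cells. *Linked*
  mode tracks whole genotypes (mutation sets) with multiplicative fitness
  and multinomial resampling at zero recombination, and is required
  whenever a planted allele has s != 0. A repeat hit at a segregating site
  joins the existing allele (no triallelic tracking; at mu = 2e-8 a third
  hit at one site is vanishingly rare).
* `selection_trajectory()` and `neutral_expectation()` - the infinite-N
  deterministic recursion and the closed-form neutral mean
  1 - (1 - mu)^t. These serve as independent oracles for the stochastic
  paths in the test-suite and as quick design aids.

## Detection sensitivity

Single-cell sequencing misses low-abundance mutations. Following the
standard five-supporting-reads convention, a site covered by c reads has
sensitivity cutoff 100 * 5 / c percent (`sensitivity_cutoff()`);
`apply_detection()` removes records below their cell's cutoff (in the long
table an absent row *is* the zero), keeps the boundary case, and drops
cells under 50x coverage. Masking is deterministic, idempotent and monotone
in coverage. A stochastic alternative (detected iff Binomial(c, p) >= 5) is
available for generator experiments but off everywhere else, since the
analyses are defined in terms of the deterministic cutoff.

Coverage comes either from an empirical per-cell list (sampled with
replacement, the way simulated cells are assigned real cells' coverages) or
from a log-normal sampler. As no empirical coverages ship with the package,
the default sampler uses median 2,000x (sdlog 0.6): a realistic single-cell
mtDNA enrichment scale that puts the median cutoff at 0.25% - deep enough
to see sub-percent heteroplasmies, shallow enough that detection limits
matter. The choice is a package default, exposed in
`detection_params()`, not an estimate of any particular dataset.

## The synthetic cohort generator

`generate_cohort()` produces multi-individual single-cell mutation tables
with ground-truth labels, so that every downstream stage can be tested
without any sequencing data. Its defaults encode the aged wild-type mouse
study condition: 5 individuals, mouse N and L, background mu = 2e-8/bp,
40 Generations. Per cell it layers:

* **background** - neutral whole-genome accumulation (marginal mode);
* **hypermutable alleles** - single sites with elevated mu and s = 0,
  emulating the OriL homopolymer indel hotspot (mouse positions 5172-5182).
  The default rate 1e-4 per replication is a package choice for "orders of
  magnitude above background", placing the allele far right on the neutral
  curve without letting it mimic drive;
* **drivers** - single sites with their own (mu, s); the default driver
  (s = 0.2, mu = 1e-7) sits inside the range the grid inference estimates
  for recurrent NCR alleles;
* **passengers** - for a `passenger_rate` fraction of cells, the driver is
  realised through a linked three-genotype model: the passenger mutation is
  planted first (one copy), and the driver is injected onto a surviving
  passenger-carrying genome at a uniformly random generation. Within such a
  cell the driver count is a subset of the passenger count, so the two
  abundances are coupled exactly as hitchhiking couples them. The passenger
  position is fixed per driver so that the same passenger allele recurs
  across cells (a recurrent driver repeatedly lands on genomes carrying
  recurrent background alleles; keeping the position fixed is what makes
  the cross-cell correlation measurable);
* **clonal alleles** - seeded at a configured abundance in a configured
  fraction of cells of *one* individual (clones arise in early development
  or are maternally transmitted, hence individual-confined), then drifted
  neutrally. Initial abundances and carrier fractions are not asserted
  quantities; they are config knobs;
* **leakage** - abundances are capped at 99% by default: fixed alleles
  read out just below 100% because wild-type signal leaks between cells in
  droplet-based library preparation;
* **detection** - masking is applied last.

What the generator does *not* emulate: sequencing or alignment artifacts,
NUMT contamination, strand bias, doublets, indel-length structure, mtDNA
copy-number variation between cells, or cell division and lineage structure.
Tests passing on synthetic cohorts therefore validate the statistical
machinery - emergence, drift, drive, linkage, masking - not robustness to
pipeline artifacts, which the upstream variant-calling conventions are
assumed to have handled.

## Allele summaries and the neutral reference curve

`summarize_alleles()` computes, per allele, the number of cells in which it
was detected (C#) and its average abundance *over detected cells only*
(AAA). Detected-cells-only averaging is essential: selection concentrates
abundance in the cells that carry the allele, while a high mutation rate
multiplies the cells without raising within-cell abundance, so the two
processes separate along the two axes.

`neutral_reference_curve()` places neutral alleles of varying mu in that
plane by direct simulation (default grid 1e-9 to 1e-3 in half-log steps).
C# is reported against the fixed simulated cell count; comparing datasets
of different sizes requires scaling C# proportionally. Hypermutable
homopolymer alleles should ride this curve; driver alleles sit above it at
matched C#, which is exactly what the generator's planted drivers do in the
test-suite.

## Driver calling

`call_drivers()` applies recurrence-of-high-abundance rules
(`driver_rule()`): wild-type mouse (>20% in >=1 cell in >=3 of 5 mice),
mutator mouse (>=3 qualifying cells in every mouse; whether each
qualifying cell must itself exceed 20% is ambiguous in prose, so both
readings are implemented behind `cells_must_exceed_threshold`, strict by
default), and human (within an individual: >=10 cells at >=50% with
strictly more cells at or above 50% than below - ties fail). The 20%
threshold is strict and the 50% threshold inclusive, following the
operators in the source rules. The caller takes the long mutation table
rather than pre-aggregated summaries because the mutator rule needs
per-individual counts of cells above threshold, which a generic per-allele
summary does not carry.

Calls are deterministic and monotone: raising any cell's abundance can
never un-call a driver (property-tested under randomised cohorts).

## Grid inference of (mu, s)

`fit_grid()` reimplements the parameter-space search: 15 half-log mutation
rates (1e-9 to 1e-2) x 21 selection coefficients (-0.5 to +0.5 in 0.05
steps) = 315 models; each model simulates `n_cells` single-site runs
(9,833 by default), assigns coverages, masks, and counts positive cells.
The half-log spacing is inferred from the published best-fit rate
3.16e-7 = 10^-6.5, which only a half-log grid produces. Models with more
than twice or fewer than half the observed positives are excluded
(boundaries inclusive - `positive_filter()`); the rest are scored by a
permutation test on the absolute difference of positive-cell abundance
means, two-sided, with the add-one estimator
p = (1 + #{permuted >= observed}) / (n_perm + 1), so p is never 0 and ties
at the maximal p are all reported. The permutation direction and estimator
are conservative standard choices where the source procedure is silent.

At desk scale (3,000 cells, a grid bracketing the truth, 200-500
permutations) the procedure recovers synthetic (1e-7, 0.2) data to within
one grid step on both axes, and no neutral model outscores the best
selected model - mutation rate alone cannot mimic driver-like abundance
distributions.

## Tissue dynamics

`simulate_tissue_mean()` averages single-cell trajectories across cells -
the bulk-tissue measurement. `fit_growth()` fits a line and a power
function y = a t^b and prefers the lower AIC. The power fit runs by
nonlinear least squares in natural space (not log-log) because early time
points can be exactly zero; starting values come from a log-log regression
on the positive points. The power form has no intercept by default
(`intercept_power = TRUE` adds one); AIC is the package's model-choice
criterion where the source figures show fits without naming one. Neutral
trajectories fit exponent ~1 (tested in [0.9, 1.1] at 10,000 cells,
mu = 1e-5); driven trajectories show positive second differences and
exponents well above 1.

## Linkage analysis

`per_cell_max_table()` reduces each cell to (max driver abundance, max
non-driver coding abundance); the "red square" (both strictly > 50%)
identifies cells where driver and coding allele must co-reside on some
genomes by the pigeonhole bound `min_coresidence(a1, a2) =
max(0, a1 + a2 - 100)`. Coding membership is interval-based (user-supplied
BED or data-frame intervals; BED is read 0-based half-open and converted to
the 1-based closed convention of mtDNA references) - consequence-level
annotation is out of scope. Only cells with at least one detected mutation
appear in the output table; red-square *fractions* of a whole cohort should
use the simulated cell count as denominator.

## Numerical and design notes

* **Determinism.** Every stochastic entry point takes a seed and is
  bit-reproducible from it; ensembles and the grid fit run from a single
  seeded stream. Unseeded calls draw from the ambient RNG state.
* **Boundary conventions.** Masking keeps abundances exactly at the
  cutoff; the positive-cell filter includes its half/double boundaries;
  the mouse 20% rule is strict, the human 50% rule inclusive; red-square
  membership is strict at 50%.
* **Degenerate inputs.** mu = 0 with no initial copies yields identically
  zero trajectories; `generations = 0` yields empty genomes; empty tables
  summarise to empty summaries; `fit_grid()` with zero observed positives
  is a usage error, and a fully filtered grid returns an empty best set
  with a warning rather than failing.
* **Problem sizes.** The shipped analyses and tests use 250-cell
  single-site ensembles at 1,600 generations, 3,195-cell whole-genome
  cohorts, cohorts of 5 x 1,500-3,000 cells for driver recovery, and
  3,000-cell grids with 200-500 permutations - sizes chosen so the full
  suite completes in minutes on one core while keeping Monte-Carlo error
  well inside the asserted tolerances. The full 315-model, 9,833-cell,
  1,000-permutation grid is the default `grid_spec()` and runs unchanged,
  just longer.
* **Known limitations.** High mutation rates without back-mutation
  overstate accumulation (inherited from the model's no-back-mutation
  assumption); marginal whole-genome mode is only exact under neutrality;
  the generator's passenger path conditions on a driver emergence rather
  than reproducing the unconditional joint law of driver emergence times;
  and abundance "leakage" is a hard cap, not a noise model.

## Session info

```{r, eval = FALSE}
sessionInfo()
```
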
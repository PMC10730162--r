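---
title: "Methods and design choices in evogut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in evogut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evogut)
```

evogut analyzes within-host evolution of a single bacterial strain in a
two-genotype gnotobiotic mouse cohort: wild-type (WT) hosts stay healthy,
IL10-deficient (KO) hosts develop intestinal inflammation, and the resident
strain accumulates mutations whose dynamics, phenotypic consequences, and
metabolic context the package quantifies. This vignette documents the
models and the choices made where the design was genuinely open.

## The de-novo / parallel mutation model

A variant call is one `(mouse, week, locus, position, ref, alt, frequency)`
observation from population (metagenomic) sequencing. Three rules turn raw
tables into evidence of adaptation:

* **Detection floor.** Calls below a minimum frequency are discarded. The
  floor defaults to 0.05 *inclusive*: a call exactly at 0.05 is kept, since
  the threshold describes the operative detection limit of
  population-sequencing pipelines rather than a strict exclusion; a
  strictly-greater switch (`variant_filter_config(inclusive = FALSE)`) is
  provided.
* **Inoculum subtraction.** A mutation is *de novo* only if its
  `(position, alt)` key is absent from the founding inoculum of that mouse.
  Keying on the alternate allele means a C>T and a C>A at the same position
  are distinct mutations — the resolution at which population sequencing
  actually distinguishes alleles.
* **Parallelism.** A locus (gene or named intergenic region, not a single
  position) is parallel-mutated when it carries qualifying calls in at
  least two mice founded from *different* inocula. Collapsing to locus
  level captures repeated hits to the same functional unit; the
  different-inoculum requirement removes the ambiguity that standing
  variants shared through a common inoculum would otherwise create.

Persistence tables match week-12 mutation sets against earlier weeks by
`(position, alt)` by default; locus-level matching is available because the
appropriate granularity depends on how hitchhiking is being interrogated,
and neither choice dominates the other.

## Inferential layer

**PERMANOVA.** One-factor, free permutation of sample labels (no strata),
pseudo-F computed from among/within sums of squared Bray-Curtis distances,
and the permutation p-value `(1 + #{F* >= F}) / (1 + n_perm)`. The
implementation is self-contained (a dozen lines of sums) and is
cross-checked in the test suite against `vegan::adonis2`, which would
otherwise be the natural choice; owning the permutation loop keeps the
seeded reproducibility contract explicit.

**PLS-DA.** NIPALS with deflation on the centered (and by default
unit-scaled) matrix against a centered one-hot group encoding. Scaling
defaults to unit variance because metabolome features span orders of
magnitude; raw-scale fits are a switch away. Significance is never read off
the PLS-DA itself — group separation is tested by PERMANOVA, and PLS-DA
loadings are used descriptively to rank contributing features. The fit is
deterministic given input order; loadings are reproducible up to the usual
sign convention.

**Univariate scans.** The package uses the two-sample Wilcoxon rank-sum
(Mann-Whitney) test for WT-vs-KO comparisons. The signed-rank variant is
sometimes named for such designs, but it is defined only for paired
samples, and a 14-vs-11 cohort has no pairing; rank-sum is the test whose
assumptions the design satisfies. Ties get midranks; small tie-free samples
use the exact null, otherwise the tie-corrected normal approximation.
Benjamini-Hochberg correction is applied across each scan
(`stats::p.adjust`), and direction comes from the median difference.

**Trajectory correlation.** Spearman correlation between focal-locus
frequency and the inflammation marker pools all `(mouse, week)` pairs in
scope rather than averaging per week: pooling uses every observation, and a
KO-only scope isolates the hosts where the sweep acts. Weeks where a mouse
has no call for the locus enter as frequency 0 (below detection), which is
what the sequencing actually observed.

## Metabolite graph and path linkage

Internal reactions project onto undirected edges between every
(substrate, product) pair — conversions, never co-substrate pairs — with
exchange and biomass reactions excluded. Reversibility is ignored for
edges: the procedure is a reachability heuristic, not a flux statement,
and an optional directed mode would only prune it. Parallel reactions merge
into one simple edge (reaction provenance retained) *before* degrees are
computed, so duplicated annotation cannot inflate weights. Edge weight is
`deg(u) + deg(v)` on that merged graph, which makes routes through
high-degree currency metabolites expensive and removes cofactor shortcuts
without hand-curating a currency blacklist — no additional pruning of
currency metabolites is performed, since the weighting already encodes the
penalty and pruning would require exactly the curation the weighting
avoids.

Path queries average the weighted lengths of up to five shortest loopless
paths (Yen's algorithm over Dijkstra, `igraph::k_shortest_paths`); the
average buffers the uncertainty of inferring pathways from topology alone.
"Length" is the weighted sum, not the hop count (a hop-count mode exists),
because degree weighting is the entire point of the construction. The
cross-dataset selection admits (screen compound, metabolome compound)
pairs whose mean length is at or below the nearest-rank 5% quantile
(`ceil(q·n)`-th order statistic of the finite lengths) of the source's
pathway set: nearest-rank is deterministic, interpolation-free, and ties at
the threshold are all admitted. Unreachable targets carry an infinite
sentinel and can never be selected. Compound-to-metabolite id mapping is an
explicit user-supplied table — name matching across Biolog/NMR/model
namespaces is dataset-specific and should never be inferred silently.

## Producibility screen

The screen asks, per source metabolite and oxygen scenario: with the
minimal medium (D-glucose removed), oxygen uptake fixed at 0, 1, or
10 mmol h⁻¹ gDW⁻¹, and the source supplied at 100 mmol h⁻¹ gDW⁻¹, can the
model secrete each target while maintaining at least 50% of its maximal
growth rate? Production is measured as the maximal flux through the
target's exchange reaction, with a demand reaction added when the target
has none — the standard producibility formulation. The call is strict:
`max flux > 1e-6`, with solver noise in `(-1e-9, 0)` clamped to zero first.
Only the optimal value is contractually defined; the flux vector is
solver-dependent under degeneracy and is never asserted on. When a scenario
supports no growth the growth constraint is vacuous (`biomass >= 0`) and
rows are flagged `zero_growth`; infeasible scenarios report all targets
non-producible with an `infeasible` status rather than erroring, so a
screen over many sources always completes. Maximum production only is
computed (the minimum is available through the same solver) because the
producibility question is about attainability.

The linear programs are solved by a dense two-phase primal simplex written
for this package (Bland's rule against cycling, explicit artificial-variable
removal, tolerance 1e-9). The problems are small — toy models are capped at
15 reactions, and even genome-scale screens solve one column per reaction —
and the test suite checks every toy optimum against an independently
formulated `scipy.optimize.linprog` (HiGHS) oracle as well as hand-derived
LP solutions.

## The synthetic-data module

The generator is the package's study design, not a test fixture. Defaults:

* **Cohort**: 14 WT + 11 KO mice, sampled at weeks 1, 4, 8, 12; experiment
  1 mice share one inoculum while experiment 2 mice get independent inocula
  (the split that makes parallelism falsifiable).
* **Sweep**: logistic trajectory with midpoint 5.5 weeks, rate
  0.9 week⁻¹, final frequency 1.0, truncated-Gaussian noise (sd 0.05,
  clamped to [0, 1]), planted only in KO mice. These values make the allele
  undetectable (< 0.05) at week 1, intermediate (~0.2, spread up to ~0.4)
  at week 4, and at or near fixation from week 8 — the canonical shape of a
  within-host sweep coupled to developing inflammation. Steeper defaults
  (e.g. rate 1.5 with midpoint 6) were rejected because they leave the
  allele essentially absent at week 4, which is not how such sweeps present
  in longitudinal data.
* **Background mutations**: 200 candidate loci; each mouse acquires a given
  locus with probability 0.2, at an onset week uniform over the sampling
  grid, persisting afterwards; frequencies are Beta(1.5, 8) (most mass
  below 0.3) with small per-week jitter. This yields a median of ~35
  de-novo mutations per mouse at week 12 and guarantees that neutral loci
  do not mimic sweeps.
* **Inoculum standing variants**: 30 per inoculum at Uniform(0.1, 0.9)
  frequencies, inherited by every sample of the corresponding mice — the
  signal that de-novo filtering must remove. The per-inoculum count is not
  an empirically constrained quantity; it is exposed in the configuration.
* **Inflammation marker**: baseline 20 units/g for both genotypes, slope
  15 units/g per week in KO and 0 in WT, Gaussian noise sd 15, floored at
  0 — a steadily rising KO marker against a flat WT baseline.
* **Feature matrices**: log-normal abundances; shifted features move their
  KO log-mean by the effect size (in within-group SD units) with random
  sign. The planted-recovery simulations use effect size 3, a strong but
  realistic separation for features called at BH-corrected p < 0.05 in
  25-sample metabolome panels.

Every generated object draws from a private stream derived from the master
seed and a stable label, so enlarging a cohort never perturbs existing
mice, and identical configurations are byte-identical.

What the generator does *not* emulate: read-level error, compositionality
of real metagenomic frequencies, linkage between background loci
(hitchhiking), temporal autocorrelation of the metabolome, or host
variation beyond the genotype effect. Passing recovery tests therefore
demonstrates that the pipeline's logic is correct under its stated model,
not that real data will be as clean.

## Numerical and degenerate-input conventions

* Frequencies and Bray-Curtis entries live in [0, 1]; all-zero sample pairs
  have undefined distance and are flagged rather than silently zeroed.
* `bh_adjust` validates p ∈ [0, 1]; all-tied features return p = 1 with
  undefined direction; Kruskal-Wallis on fully tied data returns H = 0,
  p = 1 (the tie-corrected statistic is otherwise 0/0).
* `k_shortest_mean(source == target)` returns 0 with a `same_node` flag;
  unreachable pairs return an infinite sentinel that sorts last and never
  passes selection.
* Simplex tolerance is 1e-9; producibility clamps solver noise before the
  strict 1e-6 call, and an LP reported infeasible is a status, never an
  exception.
* Trapezoid AUC requires strictly increasing times, is additive over
  contiguous partitions, and never extrapolates; blank subtraction (off by
  default, since raw OD is the common convention) floors at zero.

## Problem sizes in the shipped checks

The test suite and the acceptance script run entirely on synthetic data:
the default 25-mouse cohort with 200 background loci; 77-feature metabolome
and 94-condition phenotype matrices; 100 random graphs of at most 8 nodes
against an exhaustive path-enumeration oracle; the four toy models (≤ 15
reactions) against an independent LP oracle; 200 null replicates for
PERMANOVA calibration at 999 permutations; and 50 replicates of the
59-of-77 planted-feature recovery. These sizes give stable Monte-Carlo
estimates for every calibration claim while keeping any single check a
matter of seconds.

## Known limitations

* PERMANOVA supports the one-factor design only; no strata, no covariates.
* PLS-DA returns scores and loadings but no cross-validated error — it is
  a descriptive companion to PERMANOVA here, by design.
* The metabolite graph ignores compartments and atom mappings; a short
  path is a hypothesis generator, not evidence of a realized conversion.
* The producibility screen assumes steady state and a single objective; no
  gene-protein-reaction rules, gap-filling, or community effects.
* The simplex is dense and intended for models up to a few hundred
  reactions; genome-scale models load and screen, but a sparse solver
  would be the right tool at that scale.
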
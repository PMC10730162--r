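# evogut

Analysis toolkit for within-host experimental evolution of a single
bacterial strain in a gnotobiotic mouse model of intestinal inflammation.
It is aimed at microbial population genomicists and microbiome researchers
who track a monocolonized *E. coli*-like strain across wild-type (WT) and
IL10-deficient (KO) hosts and want to connect genomic sweeps, inflammation
markers, metabolomes, phenotype panels, and genome-scale metabolic models
in one reproducible pipeline.

## What it computes

**De-novo and parallel mutations.** Variant tables (TSV, or a breseq
GenomeDiff subset) are filtered at the detection floor (frequency ≥ 0.05 by
default), standing variants of each mouse's founding inoculum are
subtracted by `(position, alt)` key, and a locus is called *parallel* when
it is mutated in at least two mice gavaged with different inocula — the
design rule that prevents shared ancestral variation from masquerading as
repeated evolution.

**Sweep–inflammation association.** For a focal locus, pooled
`(mouse, week)` pairs of allele frequency and a fecal inflammation marker
(e.g. lipocalin-2 per gram feces) are tested with Spearman's rank
correlation, at cohort scope or restricted to KO mice.

**Group discrimination.** Bray-Curtis dissimilarity
`BC(x, y) = Σ|xᵢ − yᵢ| / Σ(xᵢ + yᵢ)` feeds a one-factor PERMANOVA with
pseudo-F

```
F = (SS_A / (k − 1)) / (SS_W / (n − k)),   p = (1 + #{F* ≥ F}) / (1 + n_perm)
```

and PLS-DA (sequential NIPALS components maximizing covariance with the
one-hot group encoding) ranks the features driving the separation.
Univariate scans use the two-sample Wilcoxon rank-sum test with
Benjamini-Hochberg correction.

**Metabolic-network linkage.** A stoichiometric model is projected onto an
undirected metabolite graph (one edge per substrate–product pair of each
internal reaction) with edges weighted by the sum of endpoint degrees, so
that high-degree currency metabolites stop acting as shortcuts. Pairs of
compounds from two datasets (e.g. a phenotype screen and a fecal
metabolome) are linked when the mean weight of their five shortest loopless
paths falls in the shortest 5% of the source's pathway set.

**Producibility screen.** Under a minimal medium with D-glucose removed,
three oxygen scenarios (anoxic 0, microaerobic 1, aerobic
10 mmol h⁻¹ gDW⁻¹), and each source metabolite supplied at
100 mmol h⁻¹ gDW⁻¹, the screen maximizes growth, constrains biomass to at
least 50% of that maximum, then maximizes each target's exchange/demand
flux; a target is producible when that maximum exceeds 1e-6.

**Phenotyping arithmetic.** Trapezoid AUC of plate-reader OD series,
replicate means, per-gram normalizations, and RPKM.

A first-class synthetic-data module generates cohorts, mutation tables with
a planted inflammation-linked sweep, inflammation series, feature matrices
with known shifted features, growth curves, and four toy metabolic models
with documented ground truth, so the whole pipeline is testable offline.

## Worked example

```r
library(evogut)

cfg    <- sim_config(seed = 1)                   # 14 WT + 11 KO mice, weeks 1/4/8/12
cohort <- generate_cohort(cfg)
mut    <- generate_mutation_tables(cfg, cohort)
denovo <- de_novo_calls(mut$calls, mut$inoculum_calls, cohort)
wk12   <- denovo[denovo$week == 12, ]

# parallelism and the univariate locus scan
par12 <- detect_parallel_loci(wk12, cohort)
m12   <- locus_frequency_matrix(wk12, mice = cohort$mouse_id)
scan  <- feature_scan(m12, factor(cohort$genotype, c("WT", "KO")))
subset(scan, adjusted_p < 0.05)
#>        feature_id statistic        raw_p   adjusted_p    direction
#> 199 mprA_upstream         0 3.990167e-06 0.0007940432 higher-in-KO

# sweep trajectory vs inflammation marker, KO mice only
infl <- generate_inflammation_series(cfg, cohort)
trajectory_correlation(mut$calls[mut$calls$locus_id == "mprA_upstream", ],
                       infl, scope = "KO-only")
#> $rho [1] 0.9136655   $p_value [1] 5.059015e-18   $n_pairs [1] 44

# group separation on the locus-frequency matrix
permanova(bray_curtis(m12), cohort$genotype, n_permutations = 999, seed = 1)
#> PERMANOVA: pseudo-F = 3.1344, p = 0.001 (999 permutations)

# producibility on a toy model: source A, target B, anoxic
scr <- production_screen(generate_toy_model("linear_chain"), fva_config(),
                         sources = "A", targets = "B")
subset(scr, oxygen == "anoxic")
#>   source target oxygen mu_max max_flux producible status
#> 1      A      B anoxic    100       50       TRUE     ok
```

The planted sweep is the only locus surviving BH correction, its frequency
tracks the KO inflammation marker (rho 0.91 over 44 mouse-week pairs), and
on the linear-chain toy the screen reports a maximal growth of 100 with
half the carbon available for target production (50) once 50% of maximal
growth is enforced — the hand-computable LP optimum.

## Package layout

| Module | Contents |
|---|---|
| `R/synthetic_data.R` | cohort, mutation, inflammation, feature-matrix, growth-curve and toy-model generators (all ground-truth-returning) |
| `R/variants.R` | variant IO, inoculum subtraction, thresholding, parallelism, persistence, locus matrices |
| `R/stats.R` | Bray-Curtis, PERMANOVA, PLS-DA (NIPALS), rank-sum scans + BH, Spearman trajectory correlation, Kruskal-Wallis |
| `R/metabnet.R` | metabolite-graph projection, degree-sum weighting, k-shortest-path means, cross-dataset pair selection |
| `R/fba.R`, `R/lp.R` | model IO (JSON / SBML subset), medium and oxygen constraints, growth maximization, producibility screen, two-phase simplex |
| `R/phenotypes.R` | trapezoid AUC, replicate means, per-gram, RPKM, condition panels, plate-reader CSV dialects |

See `vignettes/evogut-methods.Rmd` for the statistical and numerical
choices behind each module.
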
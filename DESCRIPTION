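Package: evogut
Title: Within-Host Bacterial Evolution Analysis for Gnotobiotic Inflammation Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for in vivo experimental evolution of a single
    bacterial strain in a gnotobiotic mouse model of intestinal inflammation.
    Detects de-novo and parallel mutations from population-sequencing variant
    tables, associates selective-sweep trajectories with inflammation markers,
    discriminates host-genotype groups with PERMANOVA on Bray-Curtis distances
    and partial least squares discriminant analysis, links metabolome and
    phenotype compounds over a degree-weighted metabolic network via k-shortest
    paths, screens metabolite producibility with flux balance analysis under
    oxygen scenarios, and computes growth-curve and plate phenotypes (trapezoid
    AUC, per-gram normalization, RPKM). A synthetic-data module generates
    cohorts, mutation tables with a planted sweep, inflammation series, feature
    matrices, growth curves, and toy stoichiometric models with known ground
    truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    pracma,
    stats,
    utils,
    vegan,
    xml2
Suggests:
    mixOmics,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
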
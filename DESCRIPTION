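Package: panreactome
Title: Pan-Reactome Construction and Comparative Analysis of Draft Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Merges per-species reaction sets from draft genome-scale metabolic
    models into a pan-reactome, classifies reactions by occurrence into
    near-core, intermediate and rare categories, rarefies the pan-reactome over
    random species samples and fits Heaps' law (n = k * N^gamma) to call the
    pan-reactome open or closed, computes Jaccard similarity matrices over
    reaction, ortholog and substrate-usage layers, derives cophenetic
    (patristic) distances from time-calibrated species trees, and quantifies
    the pairwise correlations among model, genotype and trait similarity and
    evolutionary distance, including within- versus between-clade comparisons
    by the Wilcoxon rank-sum test. A phylogeny-driven gain/loss simulator
    generates co-evolving reaction, ortholog and trait data so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
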
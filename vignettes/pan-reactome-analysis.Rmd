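---
title: "Pan-reactome analysis: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pan-reactome analysis: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panreactome)
```

This vignette documents the scientific model behind the package, the
parameters that matter, the numerical choices, and what the synthetic
generator does and does not emulate.

## The analysis model

A draft genome-scale metabolic model (GEM), reconstructed automatically from a
genome annotation, is treated throughout as a **set of reaction identifiers**.
This is deliberate: draft models carry no curated biomass reaction or
constraints, so flux predictions are out of scope, but reaction presence and
absence is exactly the information genome annotation supports, and set
operations on it are robust.

The pipeline has four statistical layers over a common species collection:

1. **Model layer.** Reaction identifiers from different source databases
   (KEGG, MetaCyc) are standardized against a user-supplied cross-reference
   table onto a unified namespace (MetaNetX-style) so that the same
   biochemistry merges into one column of the species × reaction occurrence
   matrix. Unmapped identifiers are kept verbatim — failing to map is loss of
   unification, not an error. The mapping must be many-to-one and terminal
   (a unified ID never re-maps to something else), which makes standardization
   idempotent.
2. **Genotype layer.** The same occurrence-matrix machinery over ortholog
   family presence.
3. **Trait layer.** Binary growth/no-growth calls over a panel of substrates,
   with missing assays allowed.
4. **Phylogeny.** A time-calibrated species tree; the pairwise evolutionary
   distance between two species is the cophenetic (patristic) distance, the
   sum of branch lengths on the path connecting them.

Similarity within the first three layers is the Jaccard index
$J(A, B) = |A \cap B| / |A \cup B|$ on the respective item sets. For traits,
each pair is first restricted to substrates scored in both species, and $J$
is taken over the growth-positive sets within that restriction, so shared
*inability* to grow does not inflate similarity and missing assays never count
as evidence. A pair whose restriction (or union of growth sets) is empty is
reported missing rather than zero.

The pan-reactome of a collection is the union of reaction sets with
per-reaction occurrence counts. Two partitions are maintained:

- **strict core / accessory** — present in *all* species vs not;
- **occurrence categories** — `NEAR_CORE` (occurrence strictly above a high
  threshold), `RARE` (strictly below a low threshold), `INTERMEDIATE`
  (inclusive in between). The default thresholds are the 24 and 316 species
  used for a 343-genome collection, rescaled proportionally to the actual
  species count. The inequalities are strict on both ends so that the
  intermediate bracket is the inclusive interval `[low, high]`; occurrence
  exactly at the high threshold is intermediate, not near-core.

## Rarefaction and Heaps' law

Rarefaction draws random species orderings without replacement and, along
each ordering, counts pan, core and accessory reactions on the first $N$
species (a *nested* design — the standard pan-genome construction — so each
permutation's pan curve is non-decreasing and its core curve non-increasing
by construction). The number of orderings (default 100) and the seed are
explicit arguments; for six or fewer species an exhaustive mode enumerates
all $n!$ orderings, making permutation means exact subset expectations.

Heaps' law $n = k N^{\gamma}$ is fitted to the per-$N$ aggregated pan counts
(mean by default; median available) by Levenberg–Marquardt nonlinear least
squares on the raw scale, initialized from the ordinary least-squares fit of
$\log n$ on $\log N$. When the log-log fit is already exact (zero residual,
as for noiseless power-law input or a constant curve) the OLS solution *is*
the least-squares optimum and is returned directly. Whether to fit aggregated
counts or per-permutation curves is genuinely open; aggregation first is the
default because it is what the fitted curve is plotted against, and both are
available since the fitter accepts any `(N, pan)` table.

The classification rule implemented is **closed iff $\gamma < 1$**. This is
the operative rule used in reactome work; note that the classical pan-genome
convention of Tettelin and colleagues instead calls a pan-genome *open* for
$0 < \gamma < 1$ under this same parameterisation, so the two conventions
disagree on names, not on the fitted number. The package reports $\gamma$
with a bootstrap confidence interval (resampling whole permutations, 200
replicates by default) as a diagnostic for "significantly below one"; the CI
never gates the call.

## Statistics

Layer correlations are plain Pearson coefficients over aligned upper-triangle
species pairs, with the $t$-transform p-value on $n-2$ degrees of freedom.
Pairwise similarity values are not independent observations — this is a
Mantel-type situation — so the pair count is always reported alongside, and a
permutation-based Mantel p-value (`mantel_permutation()`) is available as a
diagnostic. The headline numbers deliberately reproduce the plain-Pearson
computation. Correlations against evolutionary distance use the raw distance
(no similarity conversion), so a strong relationship appears as a negative
coefficient.

Two-group comparisons (within-clade vs between-clade similarity) use the
two-tailed Wilcoxon rank-sum test. The p-value is exact whenever
$\binom{n_x+n_y}{n_x} \le 10^5$, by enumerating all rank allocations with
midranks, which handles ties exactly and makes the identical-samples case
return $p = 1$ by symmetry; larger samples use the normal approximation with
tie and continuity corrections. Clades with fewer than two members, or with
an empty comparison set, are reported with a note instead of a test.

Reconstruction quality against a reference model is the confusion-matrix
accuracy $(TP+TN)/(TP+TN+FP+FN)$ over a fixed reaction universe, with the
counts returned so other metrics can be derived.

## The synthetic generator

The generator exists so that the full pipeline can be exercised, end to end,
on data whose generating process is known. It emulates the statistical
*structure* the analysis assumes — not yeast biology:

- **Tree**: pure-birth (Yule) tree conditioned on the species count, hence
  ultrametric, as for a time-calibrated phylogeny.
- **Reactions**: each non-core reaction evolves independently along the tree
  as a two-state (present/absent) continuous-time Markov chain with gain rate
  $\lambda_g$ and loss rate $\lambda_l$; over a branch of length $t$ the
  transition probabilities have the standard closed form with stationary
  presence $\pi = \lambda_g/(\lambda_g+\lambda_l)$ and relaxation
  $e^{-(\lambda_g+\lambda_l)t}$. Core reactions are fixed present everywhere.
- **Orthologs**: every reaction gets one supporting family (present exactly
  where the reaction is), plus independently evolving non-metabolic families
  that dilute the genotype–model coupling the way non-metabolic genes do.
- **Traits**: growth on a substrate requires *all* reactions in its required
  set (pathway completeness, AND-logic — chosen because trait divergence in
  this setting is driven by gaps in downstream pathways; OR-logic would make
  traits robust to single losses and nearly constant). Labels are then
  flipped with probability $\varepsilon$ (environment-like mislabelling) and
  set missing with a small probability.

### Default study conditions

The defaults are pinned in `inst/extdata/sim_config.json` and read by
`default_sim_config()`:

| parameter | default | why |
|---|---|---|
| species | 100 | large enough for stable pair statistics, small enough to run everywhere |
| universe / core | 2000 / 700 | ~35% universal reactions, matching the observed near-core share |
| $\pi$ (stationary presence) | 0.35 | accessory reactions present in roughly a third of species at equilibrium |
| $\lambda_g + \lambda_l$ | 0.3 per time unit | a 100-leaf Yule tree with unit birth rate has height ≈ ln 100 ≈ 4.6, so ≈ 1.4 expected state-change scale root-to-tip: similarity decays visibly but does not saturate across the observed distance range |
| $\varepsilon$ (trait flip) | 0.3 | strong environmental noise, so trait similarity correlates only weakly with the other layers |
| missing trait entries | 1% | a few species lack assays, as in real physiology panels |
| non-metabolic families | 1000 | genotype layer half metabolic, half independent |
| substrates × required reactions | 32 × 3 | panel size of typical substrate-usage datasets; 3-step pathways give variable traits |

Under these conditions the pipeline reproduces the qualitative correlation
structure of real draft-GEM collections — strongly negative model–distance
correlation, strongly positive genotype–model correlation, weak trait
correlations, and a closed pan-reactome — and the acceptance tests check
exactly that, over seeds 1–100.

### What passing tests do and do not show

The generator's reactions evolve independently given the tree; real reactions
co-occur within pathways, genomes experience correlated gene loss, and
horizontal transfer (absent here) can decouple gene content from phylogeny.
Trait noise is i.i.d. label flipping, not structured environmental
covariance. Passing the end-to-end tests therefore shows the *pipeline*
recovers known structure faithfully; it says nothing about whether a given
real data set satisfies these assumptions.

## Numerical choices and degenerate inputs

- Occurrence matrices are validated to be strictly binary with unique,
  non-empty row/column labels; all-zero matrices are rejected when building a
  pan-reactome (an empty pan-reactome is a contract violation, not a value).
- Species with an empty item set get missing similarity against everyone
  (including themselves): Jaccard of two empty sets is undefined and the
  caller decides, rather than silently scoring 0 or 1.
- Occurrence-category fractions are counts over a common denominator, so they
  sum to one exactly.
- Cophenetic distances are computed by one post-order traversal accumulating
  leaf depths; at each internal node, leaf pairs split across different child
  subtrees get $d(i,j) = \mathrm{depth}(i) + \mathrm{depth}(j) -
  2\,\mathrm{depth}(\mathrm{node})$. A root edge contributes to no leaf–leaf
  path and is ignored; zero-length branches are accepted, negative ones
  rejected; polytomies are handled by sequential child merging.
- Exact rank-sum enumeration compares the observed statistic with a
  $10^{-9}$ tolerance so midrank arithmetic (multiples of one half) never
  suffers from floating-point jitter.
- All generators consume a single explicit seed; the bundle generator draws
  per-stage sub-seeds from the master seed so stages stay reproducible
  individually.

## Problem sizes used in the shipped checks

The test suite and acceptance script run entirely on generated data:
$10^4$ random set pairs for the Jaccard oracle, 100 random trees of ≤ 12
leaves for the distance oracle, exhaustive rarefaction up to 6 species,
Heaps-fit recovery on curves of 100–332 sizes, full rank-sum enumeration up
to 10 observations, and one-hundred 100-species end-to-end studies (2000
reactions, 3000 ortholog families, 32 traits each). These sizes give stable
statistics for every property checked while keeping a complete run fast on a
single CPU.

## Known limitations

- No flux analysis, gap-filling, or phenotype prediction: a draft model is a
  reaction-ID set by design.
- Gene–protein–reaction strings are carried as opaque text, never parsed into
  boolean logic.
- Identifier unification is only as good as the supplied cross-reference
  table; the package performs no live database queries and does not attempt
  to reconcile conflicting mappings beyond requiring the table itself to be
  consistent.
- Plain Pearson on pairwise values inherits the non-independence caveat
  above; use the Mantel diagnostic when inference (not description) is the
  goal.
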
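# panreactome

Comparative analysis of draft genome-scale metabolic models (GEMs) across a
species collection. Automatically reconstructed draft GEMs are, for this
purpose, reaction-ID sets: merging them over hundreds of species yields a
*pan-reactome* whose structure — how many reactions are universal, how fast the
union grows as species are added, and how reaction-set similarity tracks
phylogeny, gene content and physiology — summarises the conservatism and
diversity of metabolic evolution in the group (budding yeasts being the
motivating case).

The package covers the full pipeline:

- **Reaction I/O** — read per-species reaction tables (TSV) or SBML models,
  standardize identifiers against a user-supplied cross-reference table
  (MetaCyc / KEGG → MetaNetX style), and assemble the binary species × reaction
  occurrence matrix.
- **Pan-reactome** — merge models, count per-reaction occurrence, partition
  into strict core vs accessory, classify reactions as near-core /
  intermediate / rare by occurrence thresholds, and summarise subsystems.
- **Rarefaction + Heaps' law** — nested random species sampling of pan, core
  and accessory counts, and a nonlinear least-squares fit of
  `n = k · N^γ` with an open/closed call (`γ < 1` ⇒ closed) and a bootstrap
  CI on `γ`.
- **Similarity layers** — Jaccard similarity `|A∩B| / |A∪B|` over reaction
  sets (model layer), ortholog families (genotype layer) and growth-substrate
  sets (trait layer, pairwise-complete over missing assays).
- **Phylogeny** — newick parsing and cophenetic (patristic) distances by a
  single post-order traversal.
- **Statistics** — Pearson correlations among the layers, two-tailed Wilcoxon
  rank-sum tests (exact by enumeration for small samples), within- vs
  between-clade similarity comparisons, per-clade model–trait correlations,
  and the confusion-matrix accuracy `(TP+TN)/(TP+TN+FP+FN)` for judging a
  reconstruction against a reference model.
- **Synthetic data** — a phylogeny-driven generator (Yule tree; two-state
  gain/loss Markov chains for reactions and ortholog families; substrate
  traits as noisy AND-functions of required reactions) so every stage is
  testable without external downloads.

## Worked example

```r
library(panreactome)

# a fully synthetic 100-species study, one master seed
d  <- simulate_panreactome_data(n_species = 100, seed = 1)

pan <- build_pan_reactome(d$occurrence)
pan
#> Pan-reactome over 100 species: 2000 reactions
#>   strict core: 700  accessory: 1300

curve <- rarefy(d$occurrence, n_perm = 100, seed = 1)
fit_heaps(curve, n_boot = 0)
#> Heaps' law fit: n = 1596 * N^0.05586  [CLOSED]
#>   RSS = 1.331e+05, R2 = 0.9151 over 100 sizes (mean-aggregated)

Sm <- similarity_matrix(d$occurrence, "model")
Sg <- similarity_matrix(d$orthologs, "genotype")
St <- trait_similarity(d$traits)
D  <- cophenetic_distances(d$tree)
pv <- align_layers(list(model = Sm, genotype = Sg, trait = St, dist = D))

pearson_cor(pv$model, pv$dist)$r      # -0.937  similarity falls with distance
pearson_cor(pv$genotype, pv$model)$r  #  0.991  gene content drives the model layer
pearson_cor(pv$trait, pv$model)$r     #  0.064  traits are largely decoupled
```

The three correlations read as: reaction-set similarity decays strongly with
evolutionary distance; genotype (ortholog-content) similarity and model
similarity are tightly coupled because reactions are gene-derived; trait
similarity is only weakly related to either, as expected when environment-like
noise corrupts the genotype–phenotype map. The Heaps exponent `γ ≪ 1` calls
the simulated pan-reactome closed: the reaction universe saturates as species
accumulate.

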
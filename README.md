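# fatemapExpr

Lineage-aware analysis of multi-tissue gene expression. Given a
genes-by-tissues table of linear-scale expression signals, a collection of
gene sets (GO/KEGG modules in GMT format) and a developmental *fate map* —
a rooted tree whose leaves are the assayed tissues and whose internal
nodes are embryonic stages — the package quantifies how expression
divergence grows along developmental lineage and classifies genes and
modules at every node of the map.

It is aimed at transcriptomics researchers who want to ask, for a group of
tissues that share an embryonic ancestor: which genes and which functional
modules stayed conserved, which diverged, and which remained linearly
correlated?

## The statistics at the core

* **p-rank divergence (per gene).** In each tissue, signals are converted
  to fractional ranks `p_it = rank_i / n` (ties averaged). For a tissue
  pair, gene divergence is `E_i = |p_it1 − p_it2|`; genes in the lowest 5%
  of `E` are the pair's conservatively expressed genes, and genes
  conserved in *every* pair of a node's tissue group are its ubiquitously
  conserved genes. Pairs are stratified by the fate map into
  inner/mid/outer classes (same super-node / same germ layer / different
  germ layers) and the pooled `E` distributions compared by t and KS
  tests.
* **Module distance (conservation).** For a module g of n genes,
  `D = (1/n) Σ (S_it1 − S_it2)²` on log2 signals. `D` pooled over all
  modules × pairs is fit by a normal null `N(µ, σ²)`; a node's mean
  distance `D_sub` over N pairs is referred to `N(µ, σ²/N)`, and a small
  lower-tail p flags the module as conserved in the group.
* **Module difference (KS + Stouffer).** Per pair, a two-sample KS test on
  the module's p-ranks (exact for ≤ 25 genes); per node, the pairwise
  p-values are combined by `Z_sub = Σ Φ⁻¹(p_ij) / √n`, standard normal
  under the null, with `Φ(Z_sub) < 0.05` flagging differential
  expression.
* **Module correlation.** Pearson r of log2 profiles per pair; a node is
  flagged correlated when the mean pairwise r exceeds 0.9.
* **Enrichment.** Upper-tail hypergeometric test of any interest list
  (e.g. a node's conserved genes) against each module, Bonferroni
  corrected.

A synthetic-data generator (`synthetic_spec()` /
`simulate_expression()`) produces fate-map-structured datasets — Brownian
diffusion of log2 expression along the tree, replicate columns with noise,
and planted conserved / divergent / correlated modules with ground-truth
labels — so the entire pipeline is testable without any external
download.

## Worked example

Simulate a default dataset (2000 genes, 24 tissues, 100 modules of 20
genes; 10 conserved and 10 divergent modules planted in the six-tissue
`Brain` clade), write it in the standard formats, and run the pipeline on
two nodes:

```r
library(fatemapExpr)

sim   <- simulate_expression(synthetic_spec(seed = 1))
paths <- write_synthetic_dataset(sim, "demo")

cfg <- run_config(expression    = paths[["expression"]],
                  gene_sets     = paths[["gene_sets"]],
                  fate_map      = paths[["fate_map"]],
                  fate_map_meta = paths[["fate_map_meta"]],
                  replicate_map = paths[["replicate_map"]],
                  out_dir = "demo/out", nodes = c("Brain", "Gonad"),
                  seed = 1)
res <- run_pipeline(cfg)
res$node_counts
#>    node n_leaves n_pairs n_modules conserved differential correlated
#> 1 Brain        6      15       100        90           10         93
#> 2 Gonad        2       1       100         0            0         99
res$class_comparison$summary
#>   class n_pairs n_values     mean_E
#> 1 inner      15    30000 0.06670493
#> 2   mid      70   140000 0.10672536
#> 3 outer     191   382000 0.13754934
```

Reading the output: the mean per-gene divergence `E` grows from inner
(neighbor tissues, 0.067) through mid (same germ layer, 0.107) to outer
pairs (different germ layers, 0.138) — the lineage signal the generator
plants and the method is built to detect. At the `Brain` node exactly the
10 planted divergent modules are flagged differential:

```r
div <- sim$truth$module_id[sim$truth$role == "divergent"]
head(subset(res$node_summary, node == "Brain" & module_id %in% div,
            c(module_id, D_sub, p_distance, z_sub, p_ks, differential)), 3)
#>    module_id    D_sub p_distance     z_sub         p_ks differential
#> 11      M011 6.913864          1 -8.623428 3.248942e-18         TRUE
#> 12      M012 7.543470          1 -6.857605 3.501216e-12         TRUE
#> 13      M013 6.544161          1 -8.484630 1.082034e-17         TRUE
```

Their integrated KS scores (`z_sub ≈ −7` to `−9`) are far in the lower
tail while their distances are huge (`p_distance = 1`, the opposite of
conserved), exactly the planted structure. The many "conserved" flags at
`Brain` (90/100) reflect that *any* within-clade distance is small against
a null pooled over all pairs of the whole map — node-level counts are
meaningful relative to each other and across species, not as calibrated
error rates (see the methods vignette).

Per-node conserved genes, their enrichment tables, the per-pair statistics
and the stratified divergence tests are written as TSVs under
`demo/out/`, each with a provenance header. A thin CLI wrapper for
shell use is installed at `inst/scripts/fatemap-expr.R`
(`run` / `simulate` / `compare` subcommands); two node-summary tables from
different species can be compared with `cross_species_compare()`, which
emits the percentage of significant modules per node and measure for each
species.

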
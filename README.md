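# coexhub

Weighted gene coexpression network analysis for finding trait-associated hub
genes, with a built-in synthetic-data generator so the whole pipeline is
testable without any external download.

## Who this is for

Quantitative geneticists and systems biologists who have a gene × sample
log2 expression matrix, a quantitative trait measured on (a subset of) the
samples — e.g. intramuscular fat percentage in beef cattle — and want to go
from "which genes co-vary?" to "which hub genes should I validate by
qRT-PCR?" in one scripted, reproducible run.

## The method

1. **Preprocess** — quantile-normalize samples; average probes to one row
   per gene, keeping genes measured by ≥ 2 probes.
2. **Network construction** — Pearson correlation *r* between all gene
   pairs, then either the *hard* adjacency `a_ij = 1(|r_ij| ≥ τ)` (default
   τ = 0.7) or the *soft* power adjacency `a_ij = |r_ij|^β` (default β = 7).
3. **Topological overlap** — with connectivity `k_i = Σ_u a_iu` and shared
   neighbor strength `l_ij = Σ_u a_iu a_uj`,

   ω_ij = (l_ij + a_ij) / (min{k_i, k_j} + 1 − a_ij),

   and `d_ij = 1 − ω_ij` is the clustering dissimilarity.
4. **Module detection** — average-linkage (UPGMA) clustering of `d`, cut at
   height 0.99; branches with ≥ 20 genes become modules colored in
   size-ranked order (turquoise = largest), the rest are grey.
5. **Topology & hub selection** — per-gene degree/connectivity, betweenness
   centrality `b(k) = Σ_{i≠j≠k} g_{i→j}(k)/g_{i→j}` (normalized to [0,1]),
   component-scaled closeness, clustering coefficients, plus scale-free fits
   of the degree distribution: `p(k) ∝ k^−r` and the exponentially truncated
   `p(k) ∝ k^−r e^{−αk}`, both by OLS on the log scale with R² reported.
   Candidates = union of the top genes by degree (local hubs) and by
   betweenness (global bottlenecks) — the classic 6 + 5 = 11 selection.
6. **Enrichment** — one-sided Fisher's exact (hypergeometric tail) test of
   each module against user-supplied GMT gene sets, BH-adjusted.
7. **Validation** — per-group trait means ± SEM, high/low fold change,
   covariate-adjusted regression `trait = μ + Expression + Age +
   Housekeeping + ε` per candidate gene, expression–trait correlation with
   t-transform p-values, and PCA of the candidate expression matrix.

## Worked example

```r
library(coexhub)

# a stated world: 150 genes, 3 planted modules, 60 samples
design <- synthetic_design(150, 60, module_sizes = c(60, 40, 30),
                           within_module_cor = 0.8, seed = 3)
x <- generate_expression(design)

r   <- correlation_matrix(unclass(x))
tom <- topological_overlap(soft_adjacency(r, beta = 7))
mods <- cut_modules(hierarchical_cluster(tom), height_cutoff = 0.99,
                    min_module_size = 20)
table(mods$colors)
#>      blue     brown      grey turquoise
#>        40        30        20        60

adjusted_rand_index(mods$colors, attr(x, "modules"))
#> [1] 1

module_summaries(mods, soft_adjacency(r, 7))$table
#>       color size mean_connectivity
#> 1 turquoise   60         16.614962
#> 2      blue   40          6.611434
#> 3     brown   30          6.077511
#> 4      grey   20                NA

prof <- node_topology(hard_adjacency(r, tau = 0.7))
nrow(select_candidates(prof, n_top_degree = 6, n_top_bc = 5))
#> [1] 11

group_stats(table1_fixture())
#>   group n      mean       sd      sem
#> 1   low 6  9.543333 3.318184 1.354643
#> 2  high 6 20.846667 3.734540 1.524619
```

The three planted modules are recovered exactly (ARI = 1); the largest is
colored turquoise by convention. The two-group fixture reproduces the
published validation-cohort summaries: low-marbled 9.54 ± 1.35 % and
high-marbled 20.84(67) ± 1.52 % intramuscular fat.

Or run everything at once, writing per-stage TSV/JSON/GraphML outputs and a
reproducibility manifest:

```r
run_pipeline(unclass(x), "run1", pipeline_config(seed = 3))
```

A command-line front end with `simulate-expression`, `simulate-fixture`,
`network`, `topology` and `run-all` subcommands lives at
`system.file("cli", "coexhub.R", package = "coexhub")`.

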
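---
title: "Coexpression networks, topological overlap and hub-gene validation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coexpression networks, topological overlap and hub-gene validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexhub)
```

# The model

A gene coexpression network treats genes as nodes and the strength of
expression covariation as edges. From a log2 expression matrix the package
computes Pearson correlations $r_{ij}$ and maps them to connection strengths
with one of two adjacency functions:

* **hard**: $a_{ij} = \mathbf{1}(|r_{ij}| \ge \tau)$ — a binary network;
* **soft**: $a_{ij} = |r_{ij}|^\beta$ — a weighted network in $[0,1]$.

Both are *unsigned*: negative correlations count as connections. Defaults
$\tau = 0.7$ and $\beta = 7$ follow the marbling analysis this package
operationalizes. Self-connections are excluded ($a_{ii}=0$), so the
connectivity $k_i = \sum_u a_{iu}$ never counts the gene itself.

Direct correlation is noisy; two genes in the same functional group should
also share neighbors. The topological overlap

$$\omega_{ij} = \frac{l_{ij} + a_{ij}}{\min(k_i,k_j) + 1 - a_{ij}},
\qquad l_{ij} = \sum_u a_{iu} a_{uj},$$

blends direct connection and shared-neighborhood strength; $d = 1-\omega$ is
the clustering dissimilarity. For binary adjacency $l_{ij}$ is exactly the
shared-neighbor count; for weighted adjacency the same formula is the
standard generalized form (taken at face value, as the source analysis
does). $\omega_{ii} = 1$ by convention. A numerical guard clips
floating-point drift to $[0,1]$; the brute-force oracle tests pin the
off-diagonal values to $10^{-12}$.

Modules are branches of the average-linkage (UPGMA) tree of $d$, cut at a
fixed height (default 0.99). The source method cites a "dynamic" tree cut
without parameters; this package deliberately implements the deterministic
core — static cut plus a minimum branch size — because it is reproducible
from the printed information alone, and the adaptive variant is out of
scope. `min_module_size` defaults to 20, permissive relative to the smallest
published module (38 genes). Branches below the minimum become "grey"
(unassigned), matching the field convention that grey is not a module.
Module colors are assigned in the canonical size-ranked order (turquoise,
blue, brown, yellow, green, red, black, ...), ties in size broken by the
smallest member gene id so that coloring is deterministic.

# Topology statistics and their conventions

Where a published convention was ambiguous the package picks one, documents
it, and exposes the alternative:

* **Betweenness** $b(k)=\sum_{i\ne j\ne k} g_{i\to j}(k)/g_{i\to j}$ is
  computed on the **binary** network by default (the hub tables of the
  source analysis report it for the global, hard-threshold network), and
  normalized by the $(n-1)(n-2)$ ordered pairs so values land in $[0,1]$ —
  consistent with published magnitudes of $10^{-2}$. `normalized = FALSE`
  disables the scaling, `mode = "weighted"` switches to shortest paths with
  edge length $1/a_{ij}$ (or $1-a_{ij}$).
* **Closeness** uses the component-scaled convention
  $(m/(n-1)) \cdot (m/\sum d)$ with $m$ the number of reachable nodes, which
  handles disconnected networks without infinities; isolated nodes score 0.
* **Clustering coefficient** uses the weighted formula
  $\sum_{j\ne l \ne i} a_{ij}a_{jl}a_{li} / ((\sum_j a_{ij})^2 -
  \sum_j a_{ij}^2)$, which reduces *exactly* to
  $2\,\text{triangles}/(k(k-1))$ on 0/1 input — one implementation, tested
  both ways.
* **Degree-distribution fits.** The scale-free hypothesis is assessed the
  way the source analysis does — OLS of $\log_{10} p(k)$ on $\log_{10} k$
  (power law) or on $\{\log_{10} k, k\}$ (exponentially truncated), with the
  regression $R^2$ as the fit index — not by maximum-likelihood tail
  fitting, which is a non-goal. `exponent_r` is reported as the fitted
  *slope* (so $-2$ for $p \propto k^{-2}$); $\alpha$ is converted to the
  natural-log scale. Integer degrees are binned per integer; continuous
  connectivities into equal-width bins on $\log_{10} k$ whose heights are
  probability **densities** (count divided by the linear bin width) — using
  per-bin mass instead demonstrably flattens the slope, an error caught by
  the preferential-attachment recovery test and fixed during development.

Hub candidates are the union of the top `n_top_degree` genes by degree
(local hubs) and the top `n_top_bc` by betweenness (global bottlenecks),
defaults 6 and 5 mirroring the published 11-gene selection; ties break by
the other metric, then gene id.

# Enrichment

Module-versus-gene-set over-representation uses the one-sided Fisher's exact
test, i.e. the hypergeometric upper tail for the observed overlap, with
Benjamini–Hochberg adjustment across sets (the source names only "a
corrected P-value"; BH is the package default and the method is
configurable). The universe defaults to the genes in the analyzed network —
the conservative choice when no annotation universe is given. The
EASE-style variant (overlap reduced by one) is available behind
`method = "ease"`, since some annotation tools quietly use it.

**A note on calibration testing.** The null calibration test draws random
modules and checks the fraction of p-values below 0.05. Fisher's test is
discrete: at the scale of the source network (universe of 844 genes) the
largest attainable type-I error at the 0.05 cut is only 0.019–0.039
depending on the table, so *no correct implementation* can sit inside a
binomial band around 0.05 there. The calibration test therefore uses a
genome-scale configuration (universe 20,000, module 2,000, set 1,000) where
the exact attainable level is 0.0490 and the band is meaningful. This was
computed from the hypergeometric null before the test was written, not tuned
afterwards.

# The validation stage

Candidate genes are validated against the trait on an independent two-group
cohort:

* group means, sample SD ($n-1$) and SEM of the trait;
* fold change = high-group mean / low-group mean of normalized expression
  (errors if the low mean is non-positive, where a ratio is meaningless);
* per-gene OLS regression `trait ~ expression + age + housekeeping`, the
  expression coefficient tested against the t distribution on the residual
  degrees of freedom. Rank-deficient designs are rejected with the collinear
  columns named. Expression enters raw (unstandardized) — the published
  model does not say otherwise, and raw units keep the coefficient
  interpretable;
* Pearson expression–trait correlation with the two-sided t-transform
  p-value $t = r\sqrt{(n-2)/(1-r^2)}$. The published pair (r = 0.85,
  P = 0.001, n = 12) is not exactly the two-sided t-transform value
  (0.00046); the source's convention is unstated, so this package documents
  its own and does not reverse-engineer the printed number;
* PCA of the samples × candidate-genes matrix, correlation-based by default
  because qRT-PCR expression scales differ per gene; the sign of each gene's
  PC2 loading is reported as its "relationship", the axis that separates the
  trait groups in the published biplot. Scores are centered by construction;
  variance proportions sum to one.

The printed 12-animal cohort ships as `table1_fixture()`. Its low-group
summary reproduces the published 9.54 ± 1.35 exactly; the high-group mean of
the printed per-animal values is 20.8467, whereas the published text rounds
to 20.84 — the per-animal table is taken as authoritative and the test
tolerance acknowledges the 0.007 discrepancy. The published "twelve steers
from each group" phrasing conflicts with the table's six per group; the
fixture follows the table.

# The synthetic-data generator: what it emulates

`generate_expression()` draws each planted module from a single latent
factor: $x_g = \lambda_g f_m + \varepsilon_g$, $\varepsilon_g \sim
N(0,\sigma^2)$, on a log2-intensity baseline (default 8, a typical
microarray mid-range). The loading solves
$\rho = \lambda^2/(\lambda^2+\sigma^2)$ so the *expected* within-module
correlation equals the design value — a closed form the tests verify by
Monte Carlo. Hub genes get loading $1.5\lambda$ (elevated but still
realistic; correlations stay below 1), background genes are independent
noise, and the trait is a linear function of one module's factor plus noise.

This emulates: block-correlated modules, a heavy-tailed connectivity
profile after soft thresholding, designated hubs, and a trait tied to one
module. It does **not** emulate probe-level effects, batch structure across
studies, heteroskedastic noise, or correlated background — so a green
module-recovery test establishes that the clustering machinery works on
factor-structured data, not that it would segment any real tissue panel.
The two-group fixture generator draws the trait per group from a normal
truncated at zero (negative fat is meaningless), ages uniform on the
printed 26–31-month range (no age distribution is published), and effect
genes as `expression = 0.1 + slope · trait + noise` with default slope 0.05
— the value implied by the printed low/high expression means (≈0.26→0.84)
across the group trait means (9.54→20.84).

Parameter-recovery for the regression uses a separate forward simulator
(`simulate_trait_regression`) in which the regression coefficient *is* a
generating parameter; in the two-group fixture the generative arrow points
the other way (expression depends on trait), so "recover the slope" would be
ill-posed there.

# Numerical and degenerate-input choices

* Hard-threshold boundary is inclusive ($|r| \ge \tau$ connects), stated and
  tested; the source does not specify strictness.
* Zero-variance genes abort correlation with the offending gene named —
  silently dropping rows would desynchronize gene ids.
* TOM of an all-zero adjacency is zero off-diagonal (isolated nodes share
  nothing); the denominator $\min(k)+1-a \ge 1$ can never vanish for valid
  input.
* Quantile normalization delegates to the limma implementation whose tie
  convention (tied entries share the mean reference quantile) is the one
  specified here; it is idempotent to $10^{-9}$ and rejects non-finite
  input, since the upstream summarization pipeline it mimics produces
  complete matrices.
* UPGMA delegates to `stats::hclust`; merge heights are pinned against a
  naive $O(n^3)$ agglomeration oracle. Random continuous dissimilarities
  make height ties a measure-zero event, so sorted-height comparison is
  well-defined.
* p-value underflow in near-exact regressions prints as "< 1e-15" rather
  than 0.
* All writers emit 17 significant digits so text round-trips are exact to
  $10^{-12}$ or better.
* The CLI accepts JSON configuration (not YAML) so the package depends only
  on jsonlite, which the deployment environment guarantees.

# Known limitations

* No adaptive (dynamic-hybrid) tree cutting, no module merging by eigengene
  similarity, no module-preservation statistics.
* No soft-power selection sweep: $\beta$ is a user choice, as in the source
  analysis.
* Published network-level numbers that depend on the unreleased processed
  expression matrix (global $R^2$ values, module sizes, per-gene centrality
  tables, PCA variance fractions) are not reproduction targets; the tests
  cover the machinery on synthetic data plus the printed per-animal and
  per-gene summary numbers.
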
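---
title: "woodnet: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{woodnet: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woodnet)
```

`woodnet` analyzes spatially resolved wood-formation transcriptomes: a
genes × sections expression matrix sampled along stem cryosection series
of several trees, spanning the developmental zones phloem/cambium (P/C),
expanding xylem (Ex), secondary cell wall formation (SCW) and cell death
(CD). This vignette documents the statistical machinery, the tunable
parameters and their defaults, what the synthetic-data generators do and
do not emulate, and the design decisions taken where several readings were
defensible.

## Expression preparation

Genes enter the network analysis when their VST-scale expression exceeds
`vst_threshold = 3` in at least `min_samples = 2` sections of at least
`min_trees = 3` distinct trees. Requiring support in multiple trees guards
against single-tree artifacts; the filter is idempotent and order
preserving. "Samples" is read as sections within a tree (the stricter
reading); pooling sections across trees would only relax the filter.

Profiles are scaled per gene to mean 0, variance 1 across all sections of
all trees; zero-variance rows become all zeros rather than NaN. Genes are
clustered on correlation distance (1 − Pearson r of the scaled rows) with
average linkage, sections on Euclidean distance with Ward linkage
(`ward.D2`). The linkage methods are exposed as parameters; average
linkage is the common choice for correlation distances, Ward for
Euclidean. Cutting one tree at k and k + 1 always yields nested
partitions, which the tests verify.

## Mutual information and CLR

Pairwise dependence is measured by the plug-in mutual information (in
nats) of the joint histogram after equal-frequency marginal binning with
B = min(10, ⌊√n⌋) bins. Equal-frequency (quantile) binning is robust to
the skewed distributions of expression data and makes MI exactly invariant
under strictly monotone transforms of either profile; ties are broken by
stable rank order, so every gene has identical marginal bin counts. A
zero-variance profile carries no information and scores 0 by definition.
For n = 100 and B = 10, a strictly monotone relationship attains the
maximum ln 10 ≈ 2.303 exactly, and the permutation-null expectation is
≈ 0.497 nats (computable in closed form from the hypergeometric cell
distribution; the first-order approximation (B−1)²/2n = 0.405 is a
noticeable underestimate at one expected count per cell — the acceptance
tests therefore check the exact enumeration value).

The CLR background correction converts each MI value into a two-sided
z-composite: for gene i, z_i(j) = max(0, (MI_ij − mean_i)/sd_i) with the
mean and sample standard deviation over row i excluding the diagonal, and
Z_ij = sqrt(z_i(j)² + z_j(i)²). Rows with zero spread contribute z = 0.
Genes are linked when Z_ij ≥ `threshold = 5`, the conventional cutoff for
these networks; each edge stores the CLR score and the sign of the Pearson
correlation (exact zero resolves to "+"). All filtered genes remain as
nodes, so isolation is visible rather than silently dropped. The
co-expression threshold is dimensionless; raising it can only remove
edges.

## Centrality, hubs, node categories

Shortest paths are computed on the unweighted threshold graph — CLR
weights define membership, not distances. Betweenness uses Brandes-style
fractional credit over equal-length paths, normalized by (N−1)(N−2)/2 so
values lie in [0, 1]. Closeness uses the reachable-set form
cl(v) = (r/(N−1)) · (r/S), where r is the number of vertices reachable
from v and S their total distance: on a connected graph this is the
normalized reciprocal of the sum of distances, and on disconnected graphs
(the rule rather than the exception in thresholded co-expression networks)
it stays defined and comparable, down-weighting vertices that only reach a
small component. Isolated vertices score 0 on both.

Genes are ranked descending (rank 1 = highest; ties share the minimum
rank) and the top `fraction = 0.20` by betweenness rank are hubs. The
cutoff is ⌈0.2 N⌉ and boundary ties are included in full — a tied block is
never split arbitrarily. One consequence at small network sizes: when
fewer than 20% of genes have positive betweenness, the zero-betweenness
tie enters the cutoff and hub calling becomes permissive; the acceptance
tests therefore additionally require planted hubs to rank among the
strictly positive-betweenness genes.

Node categories use a "high" threshold at the 0.80 quantile of each
metric and a betweenness-first cascade: high BTW + high Cl + high degree →
center; high BTW + high Cl → connecting; high BTW → monopole; otherwise →
edge. Combinations not literally enumerated in the four definitions
resolve to the nearest category in that priority order, and fully tied
metrics make every node "high" (hence center).

## Seed-gene modules

The module of a seed is its first-order neighborhood at the edge threshold
plus all induced edges among members — matching the per-seed module views
used for named regulators, where each panel centers on one gene. Second-
order expansion is deliberately not the default; the neighborhood order is
the natural knob to expose if needed. Raising the threshold monotonically
shrinks membership. Module overlap compares non-seed members only, and
composition summaries count TFs, hubs, responsive members and signed
edges.

## The ethylene-responsive caller

The count pipeline follows the standard limma/edgeR path. The low-count
filter implements the strict rule — a gene is dropped if *any* library has
fewer than `min_count = 10` reads — because that is the stated analysis
rule for the experiment being emulated; it is unusually stringent, so the
lenient alternative (keep genes reaching 10 in at least one library) is
available as `rule = "any"`. TMM normalization factors come from
`edgeR::calcNormFactors`; log2-CPM uses the explicit offset formula
log2((y + 0.5)/(lib·f + 1) · 10⁶) without voom precision weights — the
downstream criterion operates on fold changes and q-values, which the
moderated-t machinery supplies, and the weights would add a fitting layer
the synthetic truth cannot check.

The genewise model is ordinary least squares on the six genotype ×
treatment cell means with one ACC − mock contrast per genotype. The
original design modeled biological replicate as a random effect; here
replicates are exchangeable pools within a cell, so the cell-means fit is
the closed-form equivalent and a duplicate-correlation extension is out of
scope. Residual variances are moderated with the scaled
inverse-chi-square empirical-Bayes prior fitted by method of moments on
log variances (`limma::squeezeVar`); supplying `d0 = 0` reproduces
ordinary t-statistics exactly, and equal variances yield an infinite prior
df with variances passed through. p-values use the moderated t with
d + d₀ degrees of freedom and are BH-adjusted within each genotype
contrast separately.

A gene is *ethylene responsive* when |log2FC_WT| ≥ 1 with q_WT < 0.01 and
|log2FC_WT − log2FC_g| ≥ 1 for **both** ethylene-insensitive genotypes g —
"two-fold" mapped to one log2 unit exactly, and the receptor-dependence
clause required against both lines so that constitutive or
receptor-independent responses never qualify. The qPCR helper
`relative_expression()` implements 2^−ΔCt.

## Enrichment

Over-representation uses the one-sided hypergeometric upper tail
P(X ≥ k) for X ~ Hypergeometric(N, K, n), with the universe defaulting to
the expressed-gene set rather than the whole genome. Raw p-values at
`p_cutoff = 0.05` match the reporting convention of the emulated analysis;
BH adjustment is available but off by default. Query genes outside the
universe are dropped with a warning. Depletion is intentionally not
tested.

## Synthetic data: what it emulates, and what it does not

`generate_section_series()` emulates a four-tree cryosection series with
5 + 4 + 9 + 7 = 25 sections per tree in zone order, mirroring the relative
zone widths of real aspen series (the exact per-zone counts for the real
trees are not published; these are a modeling choice). The archetype of a
module is a Gaussian bump over section position centered in the module's
peak zone with width half the zone's extent, repeated in every tree;
members follow `coupling × archetype` (default 0.9) plus N(0, 0.3) noise
on a baseline of 6 ± 1 VST units, anticorrelated members the negated
archetype. The default configuration plants three 20-gene modules peaking
in P/C, SCW and CD among 300 genes. Each module's designated hub carries
the clean archetype with a third of the member noise plus a 0.15-strength
coupling to the other modules' archetypes, making it both the strongest
correlate of every member and the only gene with cross-module
information — the intended bridge role of a hub. The bump amplitude
(3 VST units over baseline) was chosen once as a realistic dynamic range
that also maximizes network contrast (see the limitation below).

`generate_count_experiment()` draws negative-binomial counts with
variance μ + φμ² (default φ = 0.05, the Poisson limit at φ = 0), library
sizes log-normal around 10⁶ with CV 0.1, and per-gene relative abundances
log-normal (median ≈ 300 reads). Planted responders are perturbed by
2^log2fc in the WT × ACC cell only, emulating a response that requires an
intact ethylene receptor. `generate_annotation()` plants terms that
over-represent chosen modules by a configurable odds factor over a 5%
background rate. All generators route every draw through one explicit
seed, so identical configurations are byte-identical on disk.

What the generators do **not** emulate: read-level noise and mapping
artifacts, tree-to-tree biological heterogeneity beyond independent noise,
correlated gene-gene backbone structure outside the planted modules,
batch effects, and any attempt to copy real expression values. Passing
tests on these data therefore demonstrate correctness of the machinery
and recoverability of planted structure — not performance on real wood
transcriptomes.

## Numerical choices and degenerate inputs

Zero-variance genes: MI 0 by definition, an error under Pearson clustering
(scale or filter first), an error for edge signs. CLR rows with zero
spread contribute z = 0. Bin-boundary ties are broken by stable rank
order. Exact zero correlation signs as "+". Hub boundary ties are
included; rank ties share the minimum rank. BH is applied within each
genotype contrast. The pipeline fails fast with the stage name on any
malformed input, and forbids missing values in every TSV dialect.

## Known limitation: module recovery at threshold 5 on 300 genes

The CLR z-composite has a structural ceiling at small network sizes. A
gene with k strongly elevated MI partners among G genes has row standard
deviation inflated by those same partners, bounding its z-scores at about
√(G/k); for the benchmark's 20-gene modules in a 300-gene network that is
≈ 3.9 per side, i.e. a pairwise composite of ≈ 5.4 — sitting essentially
*at* the edge threshold of 5. MI estimation noise (n = 100 sections)
then decides which within-module pairs cross it, and no choice of signal
amplitude changes this: scans over amplitudes from 0.7 to 8 VST units
plateau near 40% member recovery per hub module. At realistic scales
(tens of thousands of genes with 20-gene modules) the ceiling is ≈ 26 and
the threshold-5 network recovers modules densely; the phenomenon is a
small-G property of the CLR background correction, not of the
implementation. Hub *identification* is unaffected — planted hubs
occupy the top betweenness ranks in every tested seed — and the test
suite asserts the dense-recovery property at its stated level so the
limitation stays visible rather than papered over.

## Problem sizes used by the test suite

Unit tests run on toy graphs (≤ 12 nodes, checked against exhaustive
shortest-path enumeration), 50-gene CLR matrices against a direct two-pass
implementation, and the default 300-gene section series. Operating
characteristics of the responsive-gene caller use 2,000 genes × 18
libraries over 10 simulation seeds for the null (q < 0.01 false-positive
rate ≤ 0.02) and 10 seeds for power (planted |log2FC| = 2 in 5% of genes:
sensitivity ≥ 0.8, empirical FDR ≤ 0.05). Variance-moderation recovery
uses 5,000 genes with a known prior (d₀ = 4, s₀² = 2, recovered within
20%). Hypergeometric p-values are compared against complete enumeration
of all C(N, n) draws for N ≤ 12. End-to-end reproducibility is checked by
running the full simulate-and-analyze pipeline twice at one seed and
comparing summary JSON byte for byte.
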
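# woodnet

Network analysis of wood-formation transcriptomes in R.

Wood formation proceeds through ordered developmental zones — phloem/cambium
(P/C), expanding xylem (Ex), secondary cell wall formation (SCW) and cell
death (CD) — and spatially resolved expression series over stem cryosections
make it possible to ask which genes organize this program. `woodnet`
implements the full analysis path for such data:

* **Co-expression network inference.** Pairwise mutual information of gene
  profiles is estimated from the joint histogram under equal-frequency
  binning (B = min(10, ⌊√n⌋) bins) and background-corrected with the
  context likelihood of relatedness (CLR): for gene *i*,
  z<sub>i</sub>(j) = max(0, (MI<sub>ij</sub> − μ<sub>i</sub>)/σ<sub>i</sub>)
  over row *i*'s off-diagonal values, combined as
  Z<sub>ij</sub> = √(z<sub>i</sub>(j)² + z<sub>j</sub>(i)²).
  Genes are linked when Z<sub>ij</sub> ≥ 5; each edge carries the CLR
  score and the sign of the Pearson correlation.
* **Centrality and hubs.** Pair-normalized betweenness (BTW), closeness
  with a reachable-set correction for disconnected graphs, and degree;
  genes are ranked (rank 1 = highest) and the top 20% by BTW rank are
  called hubs, boundary ties included. Nodes are categorized as
  center / connecting / monopole / edge from high/low BTW, Cl and degree.
* **Seed-gene modules.** The threshold-5 module of a seed gene is its
  direct neighborhood plus all induced edges, with per-member hub,
  ethylene-responsiveness and TF-family flags.
* **Ethylene-responsive genes.** For a wild type + two ethylene-insensitive
  *etr1-1* receptor lines × mock/ACC count design: strict low-count filter,
  TMM normalization, log2-CPM, genewise cell-means fit, empirical-Bayes
  variance moderation, and BH-adjusted moderated t per genotype contrast.
  A gene is ethylene responsive when |log2FC<sub>WT</sub>| ≥ 1 at
  q < 0.01 and its WT response differs by ≥ 1 log2 unit from **both**
  insensitive lines.
* **Enrichment.** One-sided hypergeometric over-representation of gene
  lists against GMT gene-set collections, reported at p < 0.05.
* **Synthetic data.** Generators for a four-tree section series with
  planted zone-peaked modules and hubs, a factorial negative-binomial count
  experiment with planted WT-only responders, and annotation collections
  with planted enrichment — so the entire pipeline is testable offline
  with known ground truth.

## Worked example

```r
library(woodnet)

sim    <- generate_section_series(simulation_config(seed = 1))
series <- filter_expressed(sim$series)        # VST > 3, 2 sections, 3 trees
net    <- build_network(clr_transform(mi_matrix(series)), series, threshold = 5)
net
#> coexpression_network: 300 genes, 116 edges at CLR threshold 5

ct <- centrality_table(net)
head(ct[order(ct$btw_rank), ], 5)
#>     gene      btw     cl degree btw_rank cl_rank  hub category
#> 21 G0021 0.001625 0.0431     10        1       1 TRUE   center
#> 3  G0003 0.001010 0.0228      3        2      41 TRUE   center
#> 1  G0001 0.000943 0.0228      4        3      41 TRUE   center
#> 51 G0051 0.000904 0.0402      9        4       3 TRUE   center
#> 26 G0026 0.000810 0.0389      7        5       4 TRUE   center
```

The three planted hubs (`G0001`, `G0021`, `G0041`) occupy top betweenness
ranks; `G0021`'s threshold-5 module contains 11 genes and 15 edges:

```r
extract_module(net, "G0021", centrality = ct)
#> gene_module: seed G0021 with 11 members and 15 edges
```

Calling ethylene-responsive genes on a simulated ACC experiment with 100
planted wild-type-only responders (log2FC = 2):

```r
cexp <- generate_count_experiment(count_sim_config(seed = 2,
          responder_genes = sprintf("G%04d", 1:100)))
rt <- response_table(cexp$experiment)
sum(rt$responsive)
#> [1] 99
head(rt[rt$responsive, c("gene", "log2fc_WT", "q_WT")], 3)
#>    gene log2fc_WT     q_WT
#> 1 G0001      1.58 1.76e-06
#> 2 G0002      2.00 1.07e-09
#> 3 G0003      1.59 1.46e-06
```

99 of the 100 planted responders are recovered with no false positives:
the estimated WT fold changes sit near the planted value of 2 while both
receptor lines stay flat, which is exactly the receptor-dependence the
caller demands.

`run_pipeline(pipeline_config(seed = 1), out_dir = "out")` chains every
stage (simulate → filter/cluster → network → centrality → modules →
differential expression → enrichment) and writes all stage outputs plus a
`summary.json` and a parameter log. A thin command-line wrapper lives at
`inst/scripts/woodnet.R`.

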
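# circgrade

Circular RNAs (circRNAs) arise when a downstream splice donor is joined
back to an upstream splice acceptor, producing a closed RNA circle that is
far more stable than its linear counterpart. In bladder cancer cohorts
annotated by tumor grade (G1–G3), the expression of a circle *relative to
the linear transcript of the same locus* stratifies patients in ways the
linear transcriptome does not. circgrade is a tidyverse-native R package
for that analysis, aimed at computational biologists working with bulk
RNA-seq of graded tumor cohorts:

* **back-splice calling** from chimeric alignment records (head-to-tail
  test: same chromosome and strand, acceptor upstream of donor in
  transcription orientation), with the standard read-support filter
  (≥ 4 back-spliced reads in ≥ 1 sample);
* **genomic context** (exonic / intronic / intergenic per junction side)
  and positional bias of exonic circles over CDS and UTRs;
* **relative expression**
  `log2[(CPM_circ + 1) / (CPM_lin + 1)]`, where the linear counterpart is
  resolved from the linear splice counts at the circle's two host
  boundaries (max rule, switchable);
* **grade-wise differential analysis**: per-junction one-way ANOVA on the
  relative expression, Benjamini–Hochberg correction, set algebra against
  gene-level differential expression, and two-way average-linkage
  clustering of the discriminative matrix;
* **miRNA sponge screening**: 7/8-bp conserved target sites fully
  contained in circle intervals, with per-family recurrence ranking;
* **pathway signatures**: per-sample geometric-mean scores (smallest
  positive value as pseudo-count) correlated with circle expression,
  relative expression and parental-gene expression;
* **cross-cohort comparison**: coordinate-convention unification (0- vs
  1-based starts, pluggable liftover hook), junction matching with recall
  percentages, and grade-wise relative detection frequencies
  `freq(c, g) = (n_cg / N_c) / (N_g / N)` correlated across cohorts;
* a **synthetic cohort generator** (58 samples, 17/5/36 by grade, 94%
  exonic junctions, negative-binomial counts, grade-dependent spike-ins
  with known truth) so every stage is testable offline.

All user-facing functions take a data frame first and return tibbles, so
stages chain with the pipe; fitted cluster objects support `tidy()`,
`glance()` and `autoplot()`.

## Worked example

```r
library(circgrade)
library(dplyr)

ann <- generate_annotation(n_genes = 80, seed = 1)
co  <- generate_cohort(ann, n_junctions = 400,
                       spike = spike_config(n_spiked = 40, effect_size = 2),
                       seed = 1)

jx <- call_backsplices(co$chimeric) |>
  filter_junctions(min_reads = 4) |>
  classify_context(ann)
count(jx, context)
#>   context        n
#> 1 exonic       376
#> 2 intergenic     8
#> 3 intronic      16

re  <- quantify_relative_expression(jx, co$circ_counts, co$linear, co$samples)
res <- anova_per_feature(re, co$samples)
sum(res$adjusted_p < 0.05)
#> [1] 37

res |> arrange(adjusted_p) |>
  select(feature_id, statistic, adjusted_p, mean_G1, mean_G3) |> head(3)
#>   feature_id          statistic   adjusted_p mean_G1 mean_G3
#> 1 chr1:97879-99762:+       41.4      2.1e-09  -5.71   -3.30
#> 2 chr3:36288-39187:+       41.7      2.1e-09  -3.31   -0.95
#> 3 chr3:329726-330232:+     30.4      1.5e-07  -0.97   -3.44

cl <- cluster_matrix(re |> semi_join(res |> filter(adjusted_p < 0.05),
                                     by = c(junction_id = "feature_id")))
cl
#> <circ_clust> 37 features x 58 samples; sample groups: 22/36; feature clusters: 33/4
autoplot(cl)   # heatmap in dendrogram-leaf order, split by sample group
```

Reading the output: 400 simulated junctions are called back from the
read-level chimeric records and survive the support filter; ~94% are
exonic, matching the configured genomic mix. Thirty-seven junctions are
grade-discriminating at BH-adjusted p < 0.05 — almost all of them true
spike-ins (2 log2-unit shifts in G3): the top hits show G3 means shifted
by ~2.4 log2 units relative to G1 in either direction. Clustering the
significant matrix splits the 58 samples 22/36, i.e. the G3 samples
separate from the G1/G2 samples on relative circular expression alone.

Positional bias of the exonic circles (fractions overlap ≥ 1 bp and are
not exclusive):

```r
positional_bias(jx |> filter(context == "exonic"), ann)
#>   region n_overlapping fraction
#> 1 CDS              372    0.989
#> 2 UTR5             111    0.295
#> 3 UTR3             119    0.316
```

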
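---
title: "Grade-wise circular RNA analysis: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grade-wise circular RNA analysis: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circgrade)
library(dplyr)
```

## The problem

Back-splicing joins a downstream splice donor to an upstream splice
acceptor, producing a covalently closed circular RNA (circRNA). Because
circRNAs escape exonucleolytic decay they are attractive tissue and urine
biomarkers, and in bladder cancer their expression *relative to the linear
transcript of the same locus* carries information about tumor grade that the
linear transcriptome alone does not. circgrade implements the full
analysis chain for such a study on a cohort of tumors labeled G1/G2/G3:
junction calling from chimeric alignment records, read-support filtering,
genomic-context annotation, circular-to-linear quantification, grade-wise
differential testing and clustering, miRNA sponge-site screening, pathway
signature correlation, and cross-cohort comparison — together with a
synthetic cohort generator that provides ground truth for every stage.

## Coordinate conventions

Every interval in memory is **0-based half-open** (BED-native). Readers of
1-based dialects (the chimeric record table, GTF-lite, the linear boundary
table) subtract 1 from positions exactly once, on read; writers add it
back. Chromosome names are matched as exact strings — no silent "chr"
prefix normalization — because renaming hides genuine cohort mismatches.
`unify_coordinates()` is the one place where a foreign set's convention
(0-based vs 1-based starts) is reconciled, with a pluggable mapper hook for
genome-build liftover (identity by default; chain-file parsing is out of
scope, so build-time checks use identity and synthetic offset mappers).

## Back-splice calling

A chimeric record supports a back-splice iff both segments map to the same
chromosome and strand and the acceptor lies upstream of the donor in
transcription orientation: on `+`, donor position > acceptor position; on
`-`, the reverse. This head-to-tail test is the minimal defining property
of a back-splice; motif checks and realignment heuristics of full-scale
callers are deliberately not reproduced. Tunables:

* `max_span` (default 1 Mb): circles are typically ~0.1–4 kb, but
  annotation-spanning circles exist; the cap mainly guards against
  pathological chimeras.
* `min_reads = 4`, `min_samples = 1`: a junction is kept when at least one
  sample supports it with at least four back-spliced reads, the
  conventional high-confidence threshold for cohort studies.
* duplicate records (same sample, read id and coordinates) count once —
  PCR-duplicate robustness. Deduplication is on the full record so the
  result is invariant to input order.

Junction context is classified from the two boundary bases (the `start`
base and the `end - 1` base): exonic if inside any exon, intronic if inside
a gene body, intergenic otherwise. A junction is "exonic" only when both
sides are; the side pair is retained for origin-pair tabulations. The
positional-bias summary reports, among exonic circles, the fraction
overlapping ≥1 bp of CDS, 5'UTR and 3'UTR — the classes are not exclusive,
so the fractions do not sum to one.

## Relative expression

Counts are normalized to counts per million using the externally supplied
total library size (not the within-matrix column sum, which would make the
statistic depend on how many features were called). The linear counterpart
of a circle is resolved from the linear splice counts at its two host
boundaries; the default takes the **maximum** of the two, the conservative
choice that yields the smallest circular-to-linear ratio (`mean` and `min`
are switchable). The statistic itself is

$$\mathrm{relexpr} = \log_2 \frac{\mathrm{CPM}_{\mathrm{circ}} + 1}
{\mathrm{CPM}_{\mathrm{lin}} + 1},$$

finite everywhere by construction, antisymmetric in its arguments and zero
where circular and linear support agree.

## Differential testing and clustering

Each junction's relative expression is tested against tumor grade with a
fixed-effects one-way ANOVA. The sums of squares are computed vectorized
across features and converted to p-values with the F distribution; the
result is identical to `stats::aov` per feature (asserted in the tests)
but runs on ten thousand features in seconds. All samples enter the grade
ANOVA — muscle-invasive samples carry their G3 label — with a flag to
restrict to non-muscle-invasive samples only. Features with zero variance
within every group and equal means are assigned p = 1. Multiple testing
uses Benjamini–Hochberg (the field default; the choice is explicit in the
API), and the gene-level differential expression feeding the set algebra
uses the same ANOVA machinery on log2(CPM+1) gene counts, a documented
stand-in for a moderated linear model.

Clustering of the discriminative matrix is agglomerative with average
linkage on Euclidean distances, on both features and samples, cut at the
top split into two sample groups (A/B) and two feature clusters (1/2).
Group A is the group containing the first sample in input order — a
deterministic labeling; the partition itself is invariant to input
permutation (ties in average-linkage merges are measure-zero for
continuous data). A constant matrix has degenerate distances and is
rejected.

## miRNA sponge screening

Conserved target sites are first restricted to lengths 7–8 bp (the
canonical seed-match lengths; longer entries are a fraction of a percent of
TargetScan-scale tables). A site pairs with a circle only when **fully
contained** in the circle interval: a sponge site must lie entirely on the
circle, and "overlap within" is read as containment (an any-overlap mode is
not provided because a partially overhanging seed cannot be presented by
the circle). Strand is ignored by default, matching the strand-blind
coordinate-level procedure of interval tools; `stranded = TRUE` enables
strand matching. Sites in introns internal to an exonic circle still count
— the matching is purely genomic — but are flagged `intron_located` when an
annotation is supplied.

## Pathway signatures

A pathway's per-sample signature score is the geometric mean of member-gene
expression after adding a pseudo-count. The pseudo-count is the smallest
**strictly positive** expression value in the set's submatrix: the raw
minimum is zero whenever any member gene is silent in any sample, which
would collapse the geometric mean, so the smallest positive value is the
interpretation implemented (per-set-and-sample and per-set variants
collapse to the same choice whenever the minimum is positive). Gene
expression enters on the CPM scale, the same scale as the circles. Each
in-pathway circle contributes three correlation records: log2(CPM+1) circle
expression vs score, relative expression vs score, and circle vs parental
gene expression. Raw p-value counts are reported by default — correlation
screens in this setting conventionally report raw p < 0.05 tallies — with
an optional BH adjustment flag.

## Cross-cohort comparison

Foreign circRNA lists are unified to the internal convention, then matched
on exact (chrom, start, end) keys (strand is not compared; published lists
often omit it), with an optional per-coordinate tolerance. Grade-wise
behavior is compared through the relative detection frequency

$$\mathrm{freq}(c, g) = \frac{n_{cg} / N_c}{N_g / N},$$

the share of junction *c*'s carriers falling in grade group *g*, normalized
by the group's share of the cohort; junctions carried by fewer than three
samples are dropped. The occurrence share is normalized by the junction's
own carrier total ($n_{cg}/N_c$) rather than used raw — this makes
frequencies of different junctions comparable regardless of overall
detectability, and gives the conservation identity
$\sum_g \mathrm{freq}(c,g) \, N_g/N = 1$ (a tested invariant); the raw
reading of "occurrence divided by grade fraction" would only rescale each
junction by $N_c$ and is recoverable from the same counts. Cohorts are
correlated on their high-grade frequencies by default (the grade-specific
tendency), optionally stacking both groups.

## The synthetic cohort generator

The generator emulates the study design the pipeline targets: 58 samples
(17 G1, 5 G2, 36 G3, of which 6 muscle-invasive, all G3), several thousand
junctions with a 94/4/2 exonic/intronic/intergenic mix, and a configurable
subset of junctions whose circular-to-linear ratio shifts by grade.
Specifics:

* **Counts** are negative binomial (edgeR-style dispersion, default 0.3 —
  an overdispersion typical of heterogeneous tumor cohorts) around
  per-junction log-normal baselines, scaled by each sample's library size.
  Circular and linear boundary counts are drawn independently.
* **Baselines**: circular mean 15 counts (log-normal, sdlog 0.7), linear
  mean 150 — circRNAs are expressed roughly an order of magnitude below
  their host's linear form. Mean library size is 2×10^5 reads: CPM
  normalization makes downstream results scale-free, so a desk-scale depth
  stands in for 48M-read production libraries while keeping the full
  pipeline in seconds.
* **Spikes** multiply the circular mean by `2^(direction × effect_size)` in
  the designated grades (G3 by default), so the injected shift lives on the
  log circular-to-linear ratio and the differential truth is unambiguous.
  The empirical between-grade shift converges to `effect_size` (tested at
  200 samples per grade within 0.1 log2 units).
* **Determinism**: every output is a pure function of (configuration,
  seed). A separate `count_seed` redraws libraries and counts under the
  same junctions, baselines and spike truth, yielding replicate cohorts
  from one ground truth for cross-cohort checks.

What the generator does *not* emulate: correlated circular/linear noise at
a locus (shared transcriptional bursting), isoform structure inside a
circle, sequence content, alignment artifacts, batch effects, and
gene-gene correlation. Passing tests on this generator therefore
demonstrate the pipeline's arithmetic and statistical behavior under a
clean overdispersed count model, not performance on real libraries.

## Statistical behavior under the default conditions

Two properties of the default generator are worth stating plainly, and the
package's tests compute both rather than assuming them:

* **Calibration.** On null cohorts (no spikes) the per-feature ANOVA's raw
  p < 0.05 fraction is 0.050 at 10,000 junctions — the log-ratio of two
  pseudo-counted NB CPMs is close enough to homoskedastic normal for the
  F-test to hold its size at these group sizes.
* **Power.** With independent NB dispersion 0.3 on both the circular and
  linear components, the within-group standard deviation of the log-ratio
  has a floor of about $\sqrt{2\,\psi_1(1/0.3)}/\ln 2 \approx 1.1$–1.2
  log2 units ($\psi_1$ the trigamma function). A 1.0 log2-unit shift in G3
  against the 22 non-G3 samples then carries a noncentrality of ~3, while
  BH-adjusted significance at a ~5% spike fraction demands ~3.6–4: the
  recovery of spiked junctions at adjusted p < 0.05 averages ~0.21 over
  seeds (the acceptance suite measures it), with empirical FDR ≈ 0.03–0.09.
  Detecting 1-unit relative-expression shifts reliably at these sample
  sizes requires either lower dispersion (≤ ~0.14), correlated
  circular/linear noise (which the ratio would cancel), or larger effects;
  with `effect_size = 2` recovery is essentially complete and the spiked
  signature clusters the G3 samples into a pure group.

## Problem sizes used by the tests and acceptance script

Module tests run on cohorts of 100–1,500 junctions; the acceptance script
uses 10,000 junctions for the null calibration, five replicate 2,000
junction cohorts for recovery/FDR, a 4,571-junction cohort with a
15,223-entry synthetic reference for the cross-cohort recalls, and a
122,607-row site table for the length-filter arithmetic — sizes chosen so
the whole battery completes in about a minute on one CPU while keeping the
Monte-Carlo error of each reported fraction below its assessment tolerance.

## Known limitations

* The caller works from a simplified chimeric-record schema; it does not
  reimplement production callers' realignment or splice-motif logic, and
  cannot be compared read-for-read against them.
* The linear-count resolution rule (max over the two boundaries) is one of
  several conventions; results for lowly spliced hosts can differ between
  rules, which is why the rule is switchable and recorded.
* Gene-level differential expression is the same ANOVA as the circles, not
  a moderated model; with few samples per group, moderation would gain
  power.
* Pathway signature scoring assumes the pseudo-count interpretation above;
  sets whose members are entirely silent are rejected rather than scored.
* Enrichment against external databases (GO, KEGG, STRING) is outside the
  package's scope; the set algebra and correlation layers produce the
  inputs such tools consume.
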
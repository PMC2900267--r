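---
title: "Methods: consensus profiling of time-series transcriptomes"
author: "tempro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus profiling of time-series transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempro)
```

## Scope and data model

`tempro` implements a complete analysis chain for time-course expression
studies with unbalanced group designs, of the kind produced by microarray
profiling of a cell population sampled at a handful of post-treatment time
points. The canonical design the package targets has five time groups with
4, 6, 5, 8 and 8 arrays (days 0, 2, 7, 21 and 60 in the motivating
application, transcriptional profiling of spinal motor neurons after
injury). The pipeline starts from a genes × arrays matrix of log2-scale
expression summaries; probe-level preprocessing (background correction,
RMA summarization, probe filtering) is out of scope, as are live queries
to annotation or motif databases — annotations arrive as GMT files and
motifs as TRANSFAC or JASPAR plain-text matrices.

The stages are:

1. **Normalization** — quantile normalization across arrays, then a
   gene-wise rescaling to the interval $[-1, +1]$ used for clustering.
2. **Differential expression** — three moderated one-way ANOVA statistics,
   combined into a conglomerate ranking and thresholded at a false
   discovery rate (FDR) of 0.02.
3. **Consensus clustering** — 270 randomized K-means runs, co-occurrence
   averaging, Ward consensus cut into K (default 12) time-profile
   clusters, with optimal leaf ordering for display.
4. **Annotation enrichment** — per-cluster hypergeometric tests against
   the differentially expressed (DE) background, with 70%-overlap term
   grouping and representative-term extraction.
5. **Motif analysis** — log-odds PWM scanning of cluster promoter sets
   and binomial Z scores against the pooled DE promoter background, with
   the |Z| > 3 reporting rule, two-way clustering and PCA of the Z
   matrix.

A synthetic-data module generates all inputs with known planted structure
so every stage is testable without any download.

## Gene-wise normalization

For gene $n$ with values $y_{nm}$ on arrays $m = 1..M$,

$$\hat{y}_{nm} = \frac{y_{nm} - \bar{y}_n}{\max_m |y_{nm} - \bar{y}_n|},$$

the unique center-based rescaling that confines every gene to $[-1, +1]$
with the bound attained, so clustering sees the *shape* of the time
course rather than its magnitude. Constant genes have no direction of
change: their rows are set to zero, flagged degenerate, and excluded from
clustering. Quantile normalization maps every array onto the mean of the
order statistics; tied values within an array receive the mean of the
reference values across their shared rank span, which makes the transform
deterministic and idempotent.

## Differential expression

Each time point is treated as a separate biological condition and each
statistic tests the null of equal means across all conditions.

**Empirical-Bayes moderated F.** Per-gene residual variances $s_g^2$
(on $d_g$ degrees of freedom) are shrunk toward a prior
$(d_0, s_0^2)$ estimated by moment-matching the marginal distribution of
$\log s_g^2$ to a scaled-F law (digamma/trigamma matching with a Newton
trigamma inverse): $\tilde{s}_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$,
$\tilde{F}_g = \mathrm{MS}_{between}/\tilde{s}_g^2$ on
$(k - 1,\, d_0 + d_g)$ degrees of freedom. At $d_0 = 0$ this is the
classical ANOVA F, which the tests verify against a brute-force oracle.

**Windowed variance regularization.** A background variance
$\sigma_{0,g}^2$ is the mean of $s^2$ over a window of `window_size`
(default 101) genes ranked by mean expression, truncated at the edges;
the regularized variance weights it as `n0` (default 10)
pseudo-observations. `n0 = 0` again recovers the classical F.

**Multiclass d with permutation FDR.** The statistic is
$d_g = \sqrt{\mathrm{MS}_{between}} / (\sqrt{\mathrm{MS}_{within}} + s_0)$ —
for two groups and $s_0 = 0$ it equals $|t|$, and $d^2$ is the classical
F. The fudge factor $s_0$ minimizes the coefficient of variation of the
median absolute deviation of $d$ across standard-error quantile windows,
searched over the 0, 5, …, 100 percentiles of $s_g$. The FDR at each
observed $d$ used as a cutoff is the median over label permutations of
the count of permuted $d$ at or above the cutoff, scaled by an estimated
null proportion $\pi_0$ (the fraction of observed $d$ inside the central
50% of the permuted null) and divided by the observed count. The default
is 1,000 permutations; the replicated calibration studies below use 100
(the minimum the implementation accepts), which leaves the FDR estimate's
median stable while keeping 50-replicate studies cheap.

**FDR for the p-value tests.** P-values from the two F-type tests are
converted to FDR by maximum-likelihood fitting of a beta-uniform mixture
$\lambda\,U(0,1) + (1-\lambda)\,\mathrm{Beta}(r, s)$, with
$\mathrm{FDR}(t) = \lambda t / \hat{F}(t)$ evaluated at each gene's own
p-value and made monotone. Two safeguards matter in practice. First,
$\lambda$ is weakly identified on null data because the beta component
can absorb uniform mass; the mixture is therefore retained only when it
beats the pure-uniform model by a BIC penalty, otherwise the fit
collapses to $\lambda = 1$ (every call is a false discovery — the correct
answer on null data). Second, fewer than ten p-values cannot support a
three-parameter fit and trigger the documented Benjamini–Hochberg
fallback with a warning.

**Conglomerate ranking.** Genes are ordered by the mean of their three
per-test ranks (average ranks on ties, gene id as the final tiebreak).
The conglomerate FDR is the per-gene median of the three per-test FDRs
made non-decreasing along the conglomerate ordering; the DE set is
`fdr <= alpha` with `alpha = 0.02`. The combination rule is the simplest
order-statistic aggregate consistent with ranking genes by their degree
of significance across all three tests; it is deliberately exposed as a
documented choice rather than buried.

## Consensus clustering

K-means (Lloyd iterations, random-point initialization, empty clusters
reseeded to the farthest point, 300-iteration cap) is run 30 times for
every k in 6..14 — 270 runs — on the normalized rows of the DE genes.
The co-occurrence matrix C records the exact fraction of runs in which
each gene pair co-clustered; `1 - C` is the consensus dissimilarity,
clustered hierarchically with Ward linkage and cut into K clusters.
Applying the Lance–Williams Ward update to this non-Euclidean
dissimilarity is a deliberate, field-standard approximation. The final
membership is the tree cut itself (no re-run of K-means on the consensus
matrix). K defaults to 12 but is a user parameter; a cohesion/separation
diagnostic (mean within- vs between-cluster co-occurrence as a function
of K) is provided instead of an automatic selector, because the choice of
K in the motivating analyses was a judgment call and the package prefers
to expose it.

Leaf orders for dendrograms and heatmaps minimize the total
adjacent-leaf dissimilarity over all orderings consistent with the tree.
Up to 400 leaves an exact dynamic program over (first leaf, last leaf)
pairs per subtree is used — far above the cluster-level trees (~12
leaves) that are ordered exactly — and larger (gene-level) trees fall
back to greedy bottom-up subtree flipping. Of the two reversals of an
optimal order, the one whose first label is smaller is returned, making
the result deterministic.

## Annotation enrichment

For each cluster, each term's overlap with the cluster is tested with the
one-sided hypergeometric upper tail against the DE background (terms are
intersected with the background first). The plain hypergeometric is the
default; the EASE-style jackknife (observed count reduced by one) is a
flag. No multiple-testing correction is applied across terms — the
reporting rule is the raw p < 0.03 — and a flag exists to change that.
Significant terms are grouped by connected components of the graph whose
edges join terms with gene overlap coefficient
$|A \cap B| / \min(|A|, |B|) \ge 0.70$ on their cluster-restricted member
sets; grouping is therefore transitive. A group is significant if it
contains a term with p < 0.03, and its representative is the significant
term with the smallest background total — the most specific term, a
specificity proxy that does not require the ontology graph — with ties
broken by smaller p. The overlap coefficient (not Jaccard) is used
because term grouping is meant to capture subsumption of specific terms
by general ones.

## Motif over-representation

Counts-to-weights conversion uses pseudocount-smoothed log-odds against
the background base frequencies (estimated from the background promoter
set itself, pseudocount 0.01 of the background per column). The hit
threshold is 0.80 of the maximum achievable log-odds score; both strands
are scanned, overlapping hits all count, windows containing N never hit,
and an uninformative matrix (maximum achievable score ≤ 0) can never
produce a hit.

The over-representation null is binomial over scannable windows: with
the per-window hit rate $\hat{p}$ pooled from the background and $W$
foreground windows, $Z = (O - W\hat{p}) / \sqrt{W\hat{p}(1-\hat{p})}$.
Positive Z is over-, negative under-representation; cells with zero or
degenerate background rates are reported as missing, never as 0. The
reporting rule is |Z| > 3. The binomial null is an analytic substitute
for a full resampling null; the test suite bounds the approximation by
checking sign agreement and |ΔZ| < 0.5 against a 1,000-fold resampling
oracle on homogeneous sets (on heterogeneous, heavily planted sets the
binomial null understates promoter-level variance, which is why the
agreement bound is asserted in the homogeneous regime the null assumes).

For display, each cluster's Z vector is scaled to unit variance, motifs
and clusters are clustered two-ways (Ward on Euclidean distances) with
optimal leaf ordering, and the cluster Z vectors are projected on their
top two principal components (columns centered; each component's sign
fixed so its largest-magnitude loading is positive).

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated:

* **Expression.** Planted gene $g$ of cluster $c$:
  $y_{gm} = b_g + a\,\pi_c[\mathrm{group}(m)] + \varepsilon$ with
  baseline $b_g \sim U(4, 12)$ (log2 scale, the typical RMA summary
  range), amplitude $a = 1$ log2 unit, i.i.d. Gaussian noise with sd
  0.25 (a 4× signal-to-noise ratio), and 12 default profile shapes
  $\pi_c \in [-1,1]^5$ covering the archetypes seen in injury time
  courses (late down-regulation with varying early response, transient
  early up, sustained up, late up, down-then-up, strong early down with
  partial recovery). The shapes were chosen once so that their
  group-size-weighted, centered, max-scaled versions keep a minimum
  pairwise Euclidean distance of 1.9 — "well separated" in the sense the
  recovery tests assume. No array effects are simulated: quantile
  normalization removes them in the real pipeline, and the tests target
  the downstream mathematics.
* **Promoters.** 1200 bp (1000 up / 200 down), i.i.d. background from a
  base-composition vector (uniform by default), motif sites inserted at
  uniform non-overlapping positions on a random strand, each site drawn
  column-wise from the PWM's base distributions (so threshold
  sensitivity of the scanner is exercised, not just consensus matches).
  Site counts are Poisson: rate 0.5 per motif per promoter in the
  background — large enough that the binomial Z null has healthy counts
  — plus a planted rate (default 3) for a cluster's designated motif.
* **Annotations.** Terms draw members without replacement; planted terms
  weight their target cluster's genes by `enrichment_factor` (default 20
  in the pipeline driver), background terms draw uniformly, so
  `enrichment_factor = 1` makes planted terms statistically
  indistinguishable from background.

One master seed fans out to named per-stage child streams
(`derive_seed`), so identical configurations are byte-reproducible and
stages can be re-run in isolation.

What the generator does *not* emulate — probe-level artifacts, batch and
dye effects, correlated noise, realistic promoter composition, the
ontology DAG — bounds what passing tests show: they validate the
statistical machinery under its own assumptions, not robustness to every
artifact of real microarray data.

## Validation studies and problem sizes

The shipped tests and the acceptance script run, among others:

* an FDR calibration study — 50 replicates of a 10,000-gene, five-group
  (4/6/5/8/8) dataset with 90% null genes, checking that the realized
  false-discovery proportion among genes called at the conglomerate
  FDR ≤ 0.02 stays at or below the nominal level within Monte-Carlo
  error (100 permutations per replicate for the d statistic, as noted
  above);
* a profile-recovery study — 12 planted well-separated profiles, full
  normalize→scan→consensus path, adjusted Rand index ≥ 0.9 against the
  planted truth over 10 seeds;
* a motif reporting study — a motif planted at rate 3 in one cluster's
  promoters must exceed Z = 3 in that cluster, while non-planted
  cluster×motif cells stay within |Z| ≤ 3 in ≥ 90% of cases;
* oracle equivalences — classical-F limits of all three statistics,
  exhaustive hypergeometric enumeration, exhaustive dendrogram-order
  enumeration, naive window-scanning, and resampling Z, each against an
  independent implementation.

## Numerical and degenerate-input policies

* Within-group variances are floored at machine epsilon times the
  gene's total mean square, so noise-free fixtures give enormous but
  finite F.
* Rank ties take average ranks, with gene id as the final deterministic
  tiebreak.
* Constant genes: flagged, zeroed, excluded from clustering.
* Undefined Z cells (degenerate background rate) are missing, never 0.
* The beta-uniform fit is restarted from three fixed points with
  box-constrained parameters, BIC-guarded against the uniform model,
  and falls back to Benjamini–Hochberg (with a warning) when it cannot
  be fit.

## Known limitations

* The conglomerate combination rule (mean rank, median FDR) is a
  documented stand-in; other order-statistic aggregates are defensible.
* The binomial Z null ignores promoter-level heterogeneity; strongly
  clumped sites inflate |Z| relative to a resampling null.
* Ward linkage on `1 - C` is an approximation (the dissimilarity is not
  Euclidean).
* Term grouping implements the 70%-overlap rule directly rather than
  kappa-statistic fuzzy clustering; intent is preserved, the algorithm
  is simpler.
* Whether promoter windows should be clipped at transcript boundaries
  is a decision for whoever extracts the sequences; the package treats
  them as given and only records the window specification.
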
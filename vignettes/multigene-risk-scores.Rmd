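---
title: "Multigene risk scores for consensus molecular subtyping"
author: "ColoType package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multigene risk scores for consensus molecular subtyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ColoType)
```

## The problem

Colorectal tumors partition into four expression-defined consensus
molecular subtypes — CMS1 (immune/MSI), CMS2 (canonical), CMS3
(metabolic), CMS4 (mesenchymal) — plus an unclassified remainder, and
subtype membership is increasingly relevant to treatment choice. The
established whole-genome classifiers need hundreds of genes and fresh
cohort-level data, which rules out routine clinical use on
formalin-fixed (FFPE) material. This package implements a classifier
family built instead on a small panel of precisely measured genes: each
subtype gets a continuous score in [0, 1] from roughly ten genes,
computable for a *single* new sample against a stored reference cohort,
with a targeted RNA-seq assay in mind.

Because tumors are heterogeneous, the continuous scores are the primary
output: a sample can be positive for two subtypes at once ("mixed
type"), and the discrete label is just the maximal positive score.

## The model

### Per-gene risk scores

For a gene $g$ with bimodal expression in a training cohort $P$, a
two-component Gaussian mixture (unequal variances) partitions the
values into a low and a high mode. The *boundary* is the point between
the component means where the posterior probabilities of the two
components are equal. The mixture is refit on $B$ bootstrap resamples
of the cohort (default $B = 200$), each anchored to the full-data
boundary, giving boundaries $t_1, \dots, t_B$. The risk score of an
expression value $x$ is the empirical CDF of those boundaries,

$$ r(x) = \frac{1}{B} \#\{b : t_b \le x\}, $$

or its mirror image $\#\{t_b \ge x\}/B$ when low expression marks the
subtype. The result is an S-shaped step function whose steepness
encodes the bootstrap uncertainty of the threshold — a gene whose modes
separate cleanly yields a nearly binary variable, an uncertain gene a
gradual ramp. Orientation is chosen per subtype so that members have
the higher mean risk.

Genes whose mixture fit degenerates (component weight below 0.02, no
equal-posterior point between the means) or whose bootstrap refits fail
more than 20% of the time are rejected as not reliably dichotomizable
and never become panel candidates.

### The multigene (MRS) score

For a subtype $X$ with panel genes $g_1,\dots,g_n$, a sample's mean
risk is $r = \tfrac1n \sum_i r_i$. The continuous subtype score
calibrates $r$ by its positive predictive value in training: for sample
$v$, with $V = \{w \in P : r(w) \ge r(v)\}$,

$$ p(v) = \frac{|X \cap V|}{|V|}, $$

i.e. the fraction of samples scoring at least as high as $v$ that truly
belong to $X$. Ties in $r$ share their PPV because $V$ is defined by
$\ge$. The raw PPV sequence is made non-decreasing in $r$ by isotonic
regression (pool-adjacent-violators, equal weights; tied mean-risk
groups receive the mean of their pooled fits so equal $r$ implies equal
score) and joined by monotone piecewise-linear interpolation. Whether
to smooth before or after the PPV step is genuinely open; this package
computes PPV first and smooths second, the order that keeps the raw
PPV exactly equal to its counting definition.

Between grid points the score of a new mean risk is the score of the
*nearest training sample* (ties to the lower value) rather than an
interpolated value. This is a deliberate design choice: it makes batch
scoring and the single-sample reference path agree bit for bit.

### Thresholds, discrete calls and mixed types

Each subtype's classification threshold is the score value maximizing
the Youden index $J = \text{sensitivity} + \text{specificity} - 1$ over
all observed score values in training, smallest value on ties. A sample
is *positive* for a subtype when its score is at or above the
threshold; "at or above" (≥, not >) is chosen so the training sample
that defines the optimum is itself positive and every scanned $J$ is
attainable. The discrete label is the positive subtype with maximal
score (exact ties resolve in the fixed order CMS1 < CMS2 < CMS3 < CMS4
and are flagged), or NONE when nothing is positive; two or more
positives flag the sample as mixed type. A perfectly separated training
set can place the optimum at a score of exactly 0 or 1; the stored
threshold is nudged into the open interval (0, 1) by 1e-9, which cannot
change any call under the ≥ rule.

### Single-sample prediction and cross-platform transfer

A trained model doubles as a serialized reference set: per gene the
training expression values and risk values, per subtype the training
mean risks and calibrated scores, plus the thresholds. A new sample is
scored by (1) nearest-expression lookup of each gene's risk, (2) the
panel mean, (3) nearest-mean-risk lookup of the score, (4) thresholding
— all ties to the lower value, so the path is deterministic and
identical to scoring a one-column matrix.

Across platforms, a risk score transfers by quantile matching: each
bootstrap threshold $t$ maps to the $q$-quantile of the new cohort's
values where $q$ is $t$'s empirical quantile among the reference
training values (inverse-ECDF quantiles, so transferring onto the
reference itself is the identity). Two risk scores of the same gene are
treated as *equivalent* when the Kolmogorov–Smirnov distance between
their training risk distributions is at most 0.1 — a testable
realization of "comparable distributions" for cohorts drawn from the
same population. Thresholds always stay with the reference cohort that
defined them.

### Panel discovery across cohorts

To avoid platform-specific bias, candidate genes are evaluated
simultaneously in three training cohorts on distinct platforms. Per
cohort, a gene's oriented risk values are regressed on the 0/1
membership indicator by ordinary least squares and the gene is ranked
by the two-sided p-value of the indicator coefficient (identically the
pooled-variance t-test ordering; the regression direction follows the
source procedure and is equivalent for ranking purposes). Each gene's
triplet of per-cohort ranks is summarized by its mean; mean-rank ties
break by best single-cohort rank, then gene id. For candidate sizes
{5, 7, 10, 15, 20}, the MRS score of the top-$k$ genes is built in
every cohort and the smallest $k$ whose training AUC exceeds 0.90 in
all cohorts is selected (if none qualifies, the best-minimum-AUC size
is returned flagged).

### Derived five-class (CRCassigner-style) scores

The older five-class taxonomy is approximated by arithmetic on the CMS
scores plus one extra two-gene MRS score for the Enterocyte class
(genes CA1 and CA2): Inflammatory = CMS1-score, Goblet-like =
CMS3-score, Stem-like = CMS4-score − Enterocyte-score, TA = CMS2-score
− Enterocyte-score − CMS4-score. The discrete five-class rule
implemented here is a documented simplification: CMS1 → Inflammatory,
CMS3 → Goblet-like, CMS2/CMS4 → Enterocyte when the Enterocyte score
clears its threshold (default 0.5) and otherwise TA / Stem-like. The
original discrete decision tree conditions additionally on the
CMS4-score; its exact structure is not public, so the extra
`cms4Threshold` argument is reserved and unused by the simplified rule.

## Size-factor normalization

Targeted panels preclude total-read or gene-length normalization, so
counts are normalized against a pseudo-reference: gene $i$'s size
factor is the geometric mean of its raw counts across samples; the
scaled count is the raw count divided by that gene factor; sample $j$'s
size factor is the median of its scaled counts; and the normalized
value divides the scaled count by the sample factor. Note the last step
divides the *scaled* counts — every retained gene then has geometric
mean exactly 1 before the per-sample division — whereas the common
median-of-ratios convention divides the *raw* counts by the sample
factor only. Both are available (`conventional = TRUE` selects the
latter); the scaled-count form is the default.

Genes with a zero count in any sample would zero their geometric mean;
they are excluded from the pseudo-reference and from the medians but
remain in the matrix, scaled by a pseudocounted geometric mean
$\exp(\text{mean}(\log(c+1)))$ — on a 40-gene panel, dropping them
outright could discard panel genes. Medians of an even number of ratios
are the mean of the central pair. Modeling uses
$\log_2(\text{normalized} + 1)$ for count-derived data (pseudocount 0
is appropriate for already-continuous input).

## Numerical choices

* **EM:** two components, unequal variances; deterministic multi-start
  (k-means seeded at the outer deciles, plus splits at the upper and
  lower 15% tails, which seed a minority mode); Aitken-accelerated
  stopping at relative log-likelihood tolerance 1e-8, at most 500
  iterations; component-sd floor at 1e-3 of the data sd. Among
  converged runs that admit a boundary between the means, the highest
  log-likelihood wins. The tail starts matter: strongly unbalanced
  mixtures have a spurious heavy-tail optimum whose posterior never
  crosses 1/2 between the means.
* **Bootstrap:** resamples whose fit fails are redrawn (at most five
  rounds); all resamples are refit in one vectorized EM warm-started
  from the full-data fit — the same model and stopping rule, only
  faster. Per-gene resampling streams derive deterministically from
  (master seed, gene id), so training is reproducible to the byte.
* **Posteriors** are computed in log space so narrow components do not
  underflow.
* **Ties:** every nearest-value lookup resolves equidistant ties to the
  lower value; within-cohort p-value ties get average ranks; label ties
  follow the fixed subtype order and are flagged.
* **Serialization** writes numerics at 17 significant digits, so a
  save/load round trip reproduces scores exactly.

## The synthetic data generator

Real cohorts and gold-standard subtype calls cannot ship with a
package, so every stage is validated on a seeded generator
(`cohortSpec()`, `generateCohort()`, `generatePlatformTrio()`) that
emulates the study design: per subtype, a set of bimodal marker genes
whose high mode is shifted by `effectSize` within-component standard
deviations in that subtype's samples; subtype-independent noise genes;
and three platforms — continuous log2-scale values on two shifted/
scaled "array" platforms and negative-binomial integer counts with
log-normal library-size factors for the RNA-seq platform, so
size-factor normalization is genuinely exercised.

Defaults, chosen once as this package's notion of a realistic study:
400 samples; subtype proportions CMS1 0.17, CMS2 0.41, CMS3 0.12, CMS4
0.21, NONE 0.09 (typical of large CRC collections); 10 markers per
subtype (the selected panel size) and 20 noise genes; `effectSize = 4`
sd (≈ 2 log2 units at the within-mode sd of 0.5 — panel candidates are
by construction genes *selected* for clean bimodality, and below ~3 sd
a 10%-prevalence minority mode is not reliably recoverable by any
two-component fit); NB dispersion 0.1; library-size factors
log-normal(0, 0.3); 10% mixed-type samples receiving a second subtype's
elevation at 60% magnitude, which produces dual positivity without
changing the primary label.

What the generator does **not** emulate: probe-level microarray
effects, batch structure, FFPE degradation profiles, correlated marker
modules, or subtype-dependent library sizes. Passing the recovery tests
therefore demonstrates that the pipeline's machinery is correct and
self-consistent under its own assumptions — not that the published
accuracies on real cohorts are reproduced, which would require the
original expression data and gold-standard calls.

Test and validation problem sizes used by this package: unit tests run
on cohorts of 60–200 samples with 3-gene panels and 50 bootstrap
resamples; the end-to-end recovery study uses the full default
conditions (a 400-sample trio, 10-gene panels, 200 resamples) and a
400-sample held-out cohort.

## Known limitations

* The mixture machinery presumes an (approximately) bimodal marker;
  three-component structure is out of scope, and irregular genes are
  handled only through the boundary-hint mechanism.
* PPV calibration is the only score calibration offered (no Platt or
  beta calibration).
* Specificity in the agreement statistics is the one-vs-rest value on
  the both-classified table; published tables computed under a
  different exclusion convention may differ in the second decimal.
* The discrete five-class caller is a documented simplification of an
  unpublished decision tree.
* Risk-score equivalence across platforms assumes the cohorts sample
  comparable patient populations; quantile transfer cannot correct
  population shift, only location/scale platform effects.
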
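---
title: "Rank-based specificity scoring for unbalanced sample groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based specificity scoring for unbalanced sample groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specs)
```

## The problem

Given a genes-by-samples abundance matrix whose samples fall into several
groups (tissues, cell types, conditions), one often wants the features whose
abundance distribution is characteristic of exactly one group — either
specifically *present* there, or specifically *absent* ("disallowed").
Classical specificity indices (Tau, TSI, the Gini coefficient, per-tissue
z-scores, the Jensen–Shannon distance score) first collapse the replicates of
each group into a single summary value, discarding within-group variability,
and several of them assume balanced group sizes. Compendium-scale data sets
are strongly unbalanced — ten to hundreds of samples per tissue — and the
within-group spread is exactly what separates a cleanly specific feature from
one that merely has a high group mean.

## The score

For a feature with observations $Y_{di}$ in states $d = 1, \dots, m$, the
score of target state $d$ is an AUC-type exceedance probability

$$\hat p_d \;=\; \sum_{k \ne d} \hat P_{kd} \, \pi_k, \qquad
  \hat P_{kd} \;=\; \frac{1}{n_k n_d} \sum_{i=1}^{n_k} \sum_{j=1}^{n_d}
  \mathbb{1}\{Y_{ki} < Y_{dj}\},$$

the prevalence-weighted probability that a random observation from another
state lies strictly below a random observation from the target state. It
uses every replicate, needs no distributional assumption, and is invariant
to any monotone transform of the abundances (so normalization affects it
only through sample-depth correction, not through its scale).

Three conventions matter and are fixed throughout the package:

* **Strict ties.** The indicator is strict: tied pairs contribute 0, never
  0.5. A feature identical across all samples (for instance all-zero) scores
  0 for every state. This is what makes the score-of-zero reading of
  "specifically absent" work: an all-zero target against positive other
  groups scores exactly 0, and against all-zero other groups it also scores
  0 rather than drifting to 0.5.
* **Weight renormalization.** The weights $\pi_k$ are renormalized to sum to
  one over $k \ne d$ for each target. Without this, the attainable maximum
  would be $1 - \pi_d$ rather than 1, and perfectly separated features in
  different states would max out at different values. In equilibrated mode
  (the default) each non-target state gets weight $1/(m-1)$, which makes the
  score exactly the unweighted mean of the $m - 1$ pairwise probabilities
  and removes the influence of unbalanced group sizes entirely — duplicating
  every sample of a non-target group provably leaves the score unchanged.
* **Classification thresholds.** A feature is specifically present in every
  state scoring strictly above 0.95 and specifically absent in every state
  scoring strictly below 0.05; multiple qualifying states all get labelled.
  The thresholds are tunable in `classify_features()`; the defaults select
  features whose target distribution exceeds (or falls below) at least 95%
  of cross-group comparisons on average.

The implementation computes $\hat P_{kd}$ by binary search on the sorted
non-target values (`findInterval`), which is $O(n \log n)$ per state pair
and *exactly* equal to the brute-force double sum — the strict comparison is
a comparison of identical floating-point values, with no epsilon involved.
The test suite re-derives the double sum independently and checks equality
to $10^{-12}$ on a thousand randomized instances, and cross-checks the
two-group case against the Wilcoxon U statistic on tie-free data (the U
statistic counts ties as 1/2, so the identity only holds without ties).

## Comparator metrics

`score_all_metrics()` computes, alongside the AUC score, the five classical
indices on the per-state **mean** profile $x_1, \dots, x_n$ (replicates are
collapsed by arithmetic mean; only the AUC score sees raw replicates):

* z-score: $(x_i - \mu)/\sigma$, by default with the sample ($n-1$)
  standard deviation — the `sd_denominator` switch exposes the population
  convention, since the classical formula does not pin it down. A constant
  profile has $\sigma = 0$ and returns `NA` for every state.
* Gini: $\frac{n+1}{n} - \frac{2\sum_i (n+1-i)\,x_{(i)}}{n\sum_i x_i}$ on
  ascending-sorted values; 0 for a uniform profile, $(n-1)/n$ for one-hot.
* Tau: $\sum_i (1 - x_i/\max_j x_j)/(n-1)$, in $[0, 1]$.
* TSI: $\max_i x_i / \sum_i x_i$, in $(0, 1]$.
* JSD score: $1 - \sqrt{JS(p, e^t)}$ between the profile normalized to a
  probability vector and the idealized one-hot pattern $e^t$; entropies use
  base-2 logarithms so the Jensen–Shannon divergence — and hence the score —
  stays in $[0, 1]$ (the base is a package choice; the classical
  description leaves it open). Profiles are normalized after mean-collapse.

All-zero features yield `NA` for the ratio-based metrics rather than 0 or an
error; downstream ranking places `NA`s deterministically last.

## Normalization and the background set

`size_factors()` implements median-of-ratios depth normalization: the factor
of a sample is the median, over features with strictly positive counts in
every sample, of the ratio of its count to the feature's geometric mean. It
agrees with the DESeq2 reference implementation to $10^{-10}$ (asserted in
the tests). Note the exact equivariance: multiplying one sample's column by
$c$ multiplies its factor by $c^{(n-1)/n}$, not $c$, because the geometric
means move too; relative to the other samples the factor scales by exactly
$c$.

`select_background()` reproduces the benchmark substrate: among genes whose
overall mean normalized count lies strictly between 0.1 and 10, it keeps the
requested number (default 1000) with the smallest standard deviation across
*per-state means*. Computing the SD on per-state means rather than on pooled
samples matches the goal of between-tissue stability; both readings are
defensible, and this one was fixed as the package convention. The bounds are
exclusive and ties break by gene id, so selection is fully deterministic.

## The spike-in benchmark

`run_benchmark()` reproduces the spike-in design for comparing metrics:

1. draw `n_induced` genes (default 50) from the background and one random
   target state;
2. induce specificity: **multiply** the target-state entries by a factor
   (zeros stay zero, so background overlap can survive), or **add** a
   constant (excludes zeros and preserves the variance);
3. score every background gene with all six metrics, using the target-state
   component for the per-state metrics and the single value for
   Gini/Tau/TSI — all six are oriented "larger = more specific";
4. rank each metric over all genes (rank 1 = most specific, average ties,
   `NA`s last) and sum the induced genes' ranks; a good metric concentrates
   the induced genes in the top ranks, giving a summed rank near the
   floor $n(n+1)/2$;
5. repeat for `n_cycles` (default 5) and compare metrics by a one-way ANOVA
   on the summed ranks.

Expression overlap is quantified by `rank_sum_overlap()`: rank all samples
by decreasing abundance (1 = highest) and sum the target group's ranks; the
minimum $n_d(n_d+1)/2$ means no distributional overlap. The defining
property of the AUC score — and the headline benchmark result — is that its
score rank *tracks* this overlap: induced genes whose expression still
overlaps other tissues get visibly worse ranks, while mean-based metrics
cannot see the difference.

**Variance inflation.** To study variance sensitivity, add-mode accepts a
`variance_factor` $f$: after addition, target entries $v$ are mapped to
$m + \sqrt f\,(v - m)$ around the per-gene target mean $m$, clipped at zero
and rounded when the input matrix is integral. This is the package's own
mean-preserving construction (it multiplies the variance by exactly $f$
before clipping); the original description names no mechanism.

**Group-size stability.** `subsample_experiment()` adds a constant (default
100) to induced genes in one state, subsamples that state at fractions
0.2–1.0 without replacement, recomputes the induced genes' scores and runs
an ANOVA of score against fraction, per repeat and pooled. No trend is
expected — the score estimates a probability whose estimand does not depend
on $n_d$.

**Degenerate ANOVA rule.** When the response is numerically constant (for
example, +100 counts onto a background whose values never reach 100 gives
every induced gene a score of exactly 1 at every fraction), the usual F
statistic is 0/0 and `aov()` returns noise. The package defines the p-value
of a constant response as 1: a constant carries no evidence of any effect.
This rule is what makes "two metrics with identical ranks in every cycle
give $p \approx 1$" hold exactly.

## The synthetic generator

`simulate_counts()` emulates the benchmark substrate, not any particular
tissue atlas: negative-binomial counts with per-gene means drawn
log-uniformly from 0.1–10 (the low-abundance background regime), a shared
dispersion of 0.5 (variance $\mu + 0.5\mu^2$, squarely in the overdispersed
bulk-RNA-seq range), identical means across groups (no intrinsic
specificity), and the unbalanced-group preset `benchmark_group_sizes()`:
10 groups log-spaced from 11 to 490 samples, with a `scale` argument that
shrinks the preset proportionally for fast tests. Everything is seeded.

What it does **not** emulate: gene–gene correlation, per-tissue biology,
biotype structure, library-size variation (counts are generated on the
normalized scale, so benchmark induction is applied directly to the matrix
handed in — in a real workflow that is the normalized matrix). Passing
tests therefore demonstrate the estimator's analytic and rank-based
properties under realistic count noise, not recovery of any real tissue's
gene catalogue.

One consequence of the discrete low-abundance regime is worth knowing: with
many tied zeros the strict indicator removes probability mass from *both*
directions, so the null expectation of the score falls below 0.5 (about
0.3 at the default settings) even though no state is favoured. On
continuous-valued features the permutation-null mean is 0.5 within sampling
error, and that is how the null property is tested. At the default
thresholds the fraction of background gene–state pairs spuriously labelled
stays below 5% — mostly "absent" calls in small groups that happen to draw
all zeros, which is a genuine feature of shallow counts, not an artifact.

## Problem sizes and limitations

The test and acceptance simulations use 200 background genes over 5 groups
of 11–100 samples with 10 induced genes and 3–5 cycles — the package's
chosen desk-scale configuration, which preserves every qualitative contrast
of the full design (1000 genes, 10 groups of 11–490, 50 induced, 5 cycles)
that the functions run unchanged at full scale.

Known limitations: no correction for post-selection bias of extreme score
estimates (large estimated scores can partly reflect estimation variance;
an empirical-Bayes correction exists but is out of scope here); p-values
from specific data sets and unstated seeds are not reproduced, only the
qualitative orderings; and scores on heavily tied data are conservative by
construction, as described above.
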
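---
title: "RBF-RCE: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RBF-RCE: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbfrce)
```

## The problem

Microarray and similar transcriptomic studies routinely produce
high-dimensional small-sample data: thousands to tens of thousands of
gene-expression features measured on a few dozen specimens split into
two clinical classes. Feature selection on such data faces two coupled
difficulties. First, with far more features than samples, any flexible
classifier can overfit, so importance estimates are noisy. Second,
expression features are heavily redundant — co-regulated genes form
correlated blocks — so many nearly interchangeable feature subsets give
similar classification performance, and small perturbations of the
training set can swap one subset for another. That instability is what
makes "the selected genes" hard to interpret biologically.

`rbfrce` implements an ensemble selector, RBF-RCE, built to address
both: a bagged tree ensemble with out-of-bag (OOB) permutation
importance supplies a variance-standardized per-feature importance, and
recursive elimination of *clusters* of correlated features removes
redundancy wholesale before individual features are ranked. A
complementary stability measure, the top-k intersection metric,
quantifies how reproducible the selection is across perturbed training
sets.

## The ensemble and its importance scores

The ensemble (`fit_bit_ensemble()`) draws `n_trees` bootstrap resamples
of the $N$ samples. Each tree is a CART classification tree (Gini
impurity, no pruning, configurable depth cap) grown on its in-bag
samples; the roughly $36\%$ of samples never drawn — the expectation is
$(1 - 1/N)^N \to e^{-1}$ — form that tree's OOB set, on which its
accuracy $C_i$ is computed.

Two base learners share this contract:

* **random bits forest** (default): a layer of `n_candidate_bits`
  randomized binary intermediate features ("bits") is generated, each a
  random sparse linear combination of at most three raw features
  thresholded at a random quantile of its training distribution.
  Boosting — greedy forward selection of bits by the training logistic
  loss of an additive stump model — keeps the `n_selected_bits` most
  predictive bits, and the bagged trees are grown on this binary
  representation with per-node random bit subsampling. The three
  published ingredients (randomized nonlinear features for depth,
  boosting for breadth, bagged trees for accuracy) are retained at a
  desk-testable scale; this package does not reproduce any particular
  published implementation's internals.
* **plain forest**: trees on raw features with per-node random feature
  subsampling (`mtry = floor(sqrt(p))`) — the standard random-forest
  baseline, and the comparator used by the evaluation harness.

For a feature $f$ and tree $i$, the values of $f$ are permuted among
tree $i$'s OOB samples only, and the accuracy recomputed as $C_i^f$.
With $E_i^f = C_i - C_i^f$,

$$E^f = \frac{1}{m}\sum_i E_i^f,\qquad
  S^2 = \frac{\sum_i (E_i^f - E^f)^2}{m-1},\qquad
  \mathrm{fip} = E^f / S,$$

the importance is the mean OOB accuracy drop standardized by its
between-tree standard deviation. When $S = 0$ — in practice only when
every $E_i^f$ is exactly zero, i.e. no tree's prediction depends on
$f$ — the importance is defined as 0.

Three design choices here were fixed after the obvious naive variant
proved degenerate at $n \approx 60$:

1. **Boosting shrinkage (0.3).** Undamped Newton steps fit the training
   labels after a handful of bits, at which point forward selection has
   nothing left to rank and the kept bits reference only a few dozen raw
   features. Damping spreads the selection across the distinct signal
   directions.
2. **Coverage-balanced bit allocation.** Bit features are allocated by
   consuming successive random permutations of the feature set rather
   than independent draws, so no feature appears twice before every
   feature has appeared once. This maximizes the fraction of features
   the layer can measure at all.
3. **Per-node bit subsampling.** With all trees seeing all selected
   bits, bagging alone leaves the trees nearly identical and only the
   strongest bits ever get used; `mtry = sqrt(n_bits)` decorrelates
   them, widening the set of features with measurable importance and
   making the per-tree variance in $S^2$ meaningful.

A feature not referenced by any bit a tree splits on cannot change that
tree's predictions, so its $E_i^f$ is exactly zero; the implementation
exploits this to skip those permutations, which is what makes per-round
importance over thousands of features affordable.

The boosted bit selection is defined for two-class problems (logistic
loss); the plain forest handles any number of classes.

## Clustering and recursive elimination

Features are clustered (`cluster_features()`) under the correlation
distance $D_{ij} = 1 - r_{ij}$, with $r_{ij}$ the Pearson correlation
of the two features across samples. Rather than running K-means with a
custom metric, each feature's profile is standardized and clustered
with squared-Euclidean K-means: for standardized vectors
$\lVert u - v\rVert^2 = 2(n-1)(1-r)$, an exact monotone equivalence
(verified numerically to $10^{-9}$ in the tests). Seeding is
k-means++-style from the given seed; empty clusters are re-seeded from
the farthest point; constant features are treated as uncorrelated with
everything ($r = 0$, distance 1) instead of crashing the run.

Each elimination round (`rbf_rce()`) refits the ensemble on the
surviving features and recomputes importance. In the *cluster* phase a
feature class $S$ is scored by its best member,
$\mathrm{Score}(S) = \max_{j \in S} \mathrm{fip}^j$, and the
lowest-scoring `drop_fraction` of clusters is deleted wholesale —
redundant blocks leave together. Once fewer than `switch_threshold`
clusters remain, the *feature* phase deletes the lowest-fip
`feature_drop_fraction` of individual features per round. The final
batch is cut lowest-scores-first so the count lands exactly on
`target_features`. Ties anywhere break lexicographically on feature id,
which together with explicitly derived per-stage seeds makes the whole
run bit-reproducible.

Parameters that matter, with defaults:

| parameter | default | meaning |
|---|---|---|
| `n_trees` | 200 | ensemble size $m$; variance of $S^2$ stabilizes around 100–200 trees |
| `n_candidate_bits` | 1024 | bits generated per ensemble fit |
| `n_selected_bits` | 128 | bits kept by boosting (support of the representation) |
| `n_clusters` | $\lceil\sqrt{p}\rceil$ | feature classes at the initial clustering |
| `drop_fraction` | 0.1 | clusters deleted per cluster-phase round |
| `switch_threshold` | 30 | cluster count at which feature-level deletion starts |
| `feature_drop_fraction` | 0.1 | features deleted per feature-phase round |
| `target_features` | 50 | final subset size (set manually, as is usual for this family) |

The 10% drop fractions give geometric, roughly log-time elimination;
the cluster count and switch threshold expose the two-phase behavior at
desk scale. By default the initial partition is carried through the run
(deleted members are simply dropped); `recluster_each_round = TRUE`
re-partitions the survivors each round at $\lceil\sqrt{p}\rceil$
clusters, which costs more and in our experience changes little.

The returned ranking covers *all* original features: survivors ordered
by final-round fip, then eliminated features in reverse deletion order
(later-deleted = more important), so downstream stability analyses can
truncate at any $k$.

## The intersection metric

For two rankings truncated to their top $k$, and each prefix length
$t \le k$, the normalized prefix disagreement is

$$\delta_t = \frac{|f_i^t \setminus f_j^t| + |f_j^t \setminus f_i^t|}{2t},$$

where $f^t$ is the *set* of the first $t$ ids (order within the prefix
is deliberately ignored — this is the Fagin top-k construction). The
intersection metric is the average $\mathrm{IM} = \sum_t \delta_t / k$
and the similarity $\mathrm{sim_{IM}} = 1 - \mathrm{IM}$, both in
$[0,1]$. Lists of unequal length are an error, never silently
truncated; `truncate_ranking()` makes the truncation explicit.
`stability_report()` averages $\mathrm{sim_{IM}}$ over all pairs of a
collection of per-repeat rankings.

Two combinatorial priors explain why stability mechanically rises with
$k$: for uniformly random size-$k$ subsets of $m$ features,
$P(\text{identical}) = 1/\binom{m}{k}$ and
$P(\text{share} \ge 1) = 1 - \binom{m-k}{k}/\binom{m}{k}$, the latter
non-decreasing in $k$ and 1 as soon as $2k > m$. Both are computed in
log space and verified against exhaustive enumeration in the tests.

One empirical subtlety the tests make visible: selectors with a stable
signal head and a noisy tail are *not* monotone at small $k$ — the
curve rises while $k$ covers the reproducible head, dips as the noisy
tail dilutes it, and then rises again toward 1 as $k$ approaches $p$
(where the prefix sets must coincide). The increasing-trend claim holds
in the upper range of $k$, which is where the evaluation harness's
default grids sit.

## The evaluation harness

`run_evaluation()` repeats, `n_repeats = 10` times: a stratified
2/3–1/3 holdout split; feature selection on the training split only;
a refit of the same ensemble family on the selected top
`target_features`; test-split accuracy. Stratification is used because
at $n \approx 60$ unstratified splits regularly lose a class; per-class
training counts are clamped so both splits always contain both classes.
The per-repeat full rankings feed `stability_curve()`. The final
classifier after selection is the same ensemble family as the selector,
keeping the comparison between selectors about the *selection*, not
about a second classifier.

## The synthetic generator

`simulate_expression()` emulates the shape of two-class microarray
case studies (thousands of features, tens of samples): each feature
belongs to one of `n_blocks` blocks and is
$\sqrt{\rho}\,b + \sqrt{1-\rho}\,\varepsilon$ (Gaussian latent factors,
scaled by `noise_sd`), giving exact within-block correlation $\rho$ in
expectation; class labels are Bernoulli; the `n_informative` planted
features get a mean shift of `effect_size` noise-SDs in the case class.
Informative features are spread round-robin across blocks at a random
position within each block, so their identifiers carry no positional
signal a tie-break could accidentally exploit. Defaults
(60 samples × 2000 features, 20 informative, 50 blocks, $\rho = 0.6$,
effect 1.5, balanced classes) mirror the canonical colon-cancer-sized
benchmark shape.

What it deliberately does not model: intensity-dependent variance,
batch effects, non-Gaussian marginals, label noise, or informative
features whose *block* (rather than the feature itself) carries the
class signal. Passing tests on this generator therefore demonstrate
correct mechanics and sensible behavior under redundancy, not
performance on real microarray noise.

## Problem sizes and numerical choices

The test suite and the reproduction script run at sizes a laptop core
handles in minutes: ensembles of 100–200 trees, bit budgets of
512–1024 candidates / 64–128 selected, selection problems up to
2000 × 60, and 10-repeat holdout evaluations on 500 × 60 data. At
these sizes the end-to-end selector recovers roughly two-thirds of
planted informative features at a 2-SD effect, and the holdout
accuracy of the top-50 refit sits in the high 0.8s.

Degenerate inputs are handled explicitly: constant features (no valid
bit threshold → bit resampled, then dropped; correlation distance 1),
empty OOB sets (tree kept but excluded from importance averaging),
zero-variance importance (fip 0), empty K-means clusters (re-seeded
from the farthest point), and single-class labels (error). All
randomness flows from explicit integer seeds through a deterministic
seed-derivation scheme, so identical inputs give bit-identical
rankings, reports and curves.

## Known limitations

* The random-bits learner is a simplified variant; absolute accuracies
  will differ from any published random-bits-forest implementation.
* The boosted bit selection is binary-class only.
* Importance support per round is bounded by
  `3 * n_selected_bits` raw features; on very wide matrices early
  rounds measure only a subset of features per round (fresh layers each
  round rotate the coverage, and the balanced allocation maximizes it).
* No automatic choice of `target_features`; the subset size is a study
  decision.
* Wall-clock comparisons to other selectors are out of scope; nothing
  here is tuned for large $n$.
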
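---
title: "One-class nearest-neighbor classification with oclab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-class nearest-neighbor classification with oclab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oclab)
```

## The problem

Severely imbalanced biomedical datasets — a few dozen poor-outcome patients
against hundreds of ordinary ones, a handful of rare-protein examples in a
yeast assay — often cannot support an ordinary two-class classifier. The
minority class is too small to characterize, or was not yet observed at all
when the model had to be deployed. The one-class framing trains on the
majority ("target", labeled `negative` here) class alone and asks, for each
new point $z$, whether it looks like that class:

$$f(z) = \big[\, d(z) < \theta \,\big],$$

where $d(z)$ is a dissimilarity between $z$ and the target class and
$\theta$ a threshold. Everything in this package is an instantiation of
that rule, with minority ("positive") points being whatever the rule
rejects.

## The OCNN family

The OCNN score compares two neighborhood scales. For a test point $z$ and
target-class training set:

* $D_J$ — the mean Euclidean distance from $z$ to its $J$ nearest training
  points;
* $D_K$ — the mean distance from each of those $J$ neighbors to its own
  $K$ nearest training neighbors (the neighbor itself excluded, since its
  distance to itself is zero and would collapse the denominator).

$z$ is accepted as target class when $D_J / D_K < \theta$. The named
variants fix the counts: 11NN ($J=K=1$), 1KNN ($J=1$), J1NN ($K=1$), and
the general JKNN. Averaging more second-stage neighbors ($K$) inflates the
denominator and loosens the rule; averaging more first-stage neighbors
($J$) inflates the numerator and tightens it — the two counts act like an
implicit threshold, which is why `make_variant()` treats $\theta$, $J$ and
$K$ as one configuration.

Degenerate geometry is resolved by ratio semantics rather than arithmetic
accidents: $D_J = 0$ (the test point coincides with a training point)
scores 0 and is accepted at any positive threshold; $D_K = 0$ with
$D_J > 0$ (duplicated training points) scores `Inf` and is rejected at any
finite threshold. Neighbor ties are broken toward the lowest row index so
that every result is reproducible.

## KMOR: clustering with an outlier cluster

Plain K-means lets one far point drag a center. K-means with outlier
removal (KMOR) adds a $(k{+}1)$-th cluster that absorbs points farther
from every center than a data-driven threshold

$$D(U, Z) = \gamma \cdot
  \frac{\sum_{\text{non-outliers}} \lVert x_i - z_{a_i}\rVert^2}{n - n_{\text{out}}},$$

i.e. $\gamma$ times the current mean non-outlier squared distance, with the
outlier count capped at $n_0 = \lfloor \texttt{n0\_fraction} \cdot n \rfloor$.
The objective is
$P(U,Z) = \sum_{\text{non-outliers}} \lVert x_i - z_{a_i}\rVert^2
 + n_{\text{out}} D(U,Z)$, and the fit alternates assignment and center
updates from a seeded random initialization of $k$ distinct rows.

Two numerical decisions deserve attention:

* **The assignment step is implemented as an exact coordinate
  minimization.** The textbook phrasing — "outlier iff nearest squared
  distance exceeds $D(U,Z)$, at most $n_0$ of them" — oscillates at the
  decision boundary: a point whose distance is *just below* $D$ can still
  lower $P$ as an outlier, so the literal threshold test may pull it back
  and forth and raise the objective by a fraction of a percent. `kmor_fit()`
  instead assigns the $m$ farthest points to the outlier cluster, with
  $m \le n_0$ chosen to minimize $P$ given the current centers. Away from
  the boundary this coincides with the threshold test; at the boundary it
  is the choice under which the objective provably never increases, which
  is the form in which the algorithm's convergence is established in the
  clustering literature. The fitted object still reports the final
  $D(U,Z)$ (`d_threshold_final`, in squared-distance units) and flags when
  the $n_0$ cap truncated the outlier set (`cap_applied`).
* **Empty clusters are re-seeded** with the farthest current non-outlier
  point, the standard K-means repair; this too can only decrease the
  objective.

The convergence tolerance `delta` (absolute, on $P$) defaults to `1e-6`,
far below any meaningful change at the problem sizes involved; `itermax`
defaults to 100. A single run is a local optimizer — initializations that
seed a center on an outlier converge elsewhere — so `kmor_select_k()` runs
`n_restarts = 5` seeded restarts per candidate $k$ and keeps the best
objective. Note that $P$ typically *decreases* as $k$ grows, so selecting
$k$ by minimum objective is meaningful only over a deliberately bounded
candidate list (default `1:3`); the full objective-vs-$k$ curve is
returned so the choice can be inspected rather than trusted.

$\gamma$ defaults to 2.5 and `n0_fraction` to 0.05 — the configuration
used throughout the package's reference experiments (the experiment tables
list $\gamma$ under the name $\lambda$).

## Tuning from one class: proxy outliers

With no non-target data, $(J, K)$ and $\theta$ cannot be cross-validated
directly. The package's tuning module manufactures a stand-in binary
problem: detect outliers *within* the target training data and relabel
them `proxy-outlier`. Two detectors are available:

* `iqr` — flags points whose nearest-neighbor distance exceeds
  $Q_3 + 1.5\,\mathrm{IQR}$ of the 1-NN distance distribution. Fences on
  distances, not on individual features: per-feature fences flag marginal
  extremes that are not distance outliers, and the classifiers downstream
  are distance-based. The detector is documentedly blind to *tight pairs*
  of far outliers (each is the other's nearest neighbor at distance 0).
* `kmor` — the outlier cluster of a KMOR fit, which has no such blind spot
  and respects multi-cluster structure.

`optimize_jk()` grid-searches $(J,K)$ (default $\{1..10\}^2$) by stratified
inner cross-validation (default 2 folds): each fold fits JKNN with
$\theta = 1$ on the target-labeled part and scores G-means on the held-out
mix; ties go to the smallest $J$, then $K$. Cells unfittable in some fold
($J + K$ exceeding the fold's target count) are excluded rather than
scored. `optimize_theta()` computes, for every validation point, the
candidate ratio $D_1/D_{11}$; each pooled candidate is then evaluated as an
11NN threshold over the same folds and the best G-means wins, ties to the
smallest candidate. The final evaluation deliberately reuses the same fold
assignment that produced the candidates: the candidates *are* the
validation scores, so re-using the folds makes the scan an exact
re-thresholding of known numbers rather than a second noisy estimate.

Two consequences are worth stating honestly. First, on a cleanly separable
construction the chosen $\theta$ *equals* the smallest proxy ratio (it must
be one of the candidates), sitting strictly above every target ratio.
Second, when the target class is clean, the detectors still flag its
distance tail — up to the $n_0$ cap for KMOR — so proxy-based tuning is
biased toward rejecting the tail of the very class it is trying to accept.
This is visible in the package's end-to-end tests: tuned JKNN reaches mean
G-means around 0.93 on a construction where an oracle choice of $(J,K)$
reaches 0.98. The bias is a property of the method, not of the
implementation, and it is strongest in low dimension where the Gaussian
tail beyond $\gamma \times$ the mean squared distance is heaviest.

When a scan is degenerate (no proxies, or no finite ratios), tuning falls
back to $J = K = 1$ and `theta_fallback = 1.5` with a warning. The
fallback value mirrors the reference experiments' fixed-threshold setting
$\omega = 1.5$ for the threshold variants, a configuration constant whose
role is otherwise undocumented; it is therefore exposed as an explicit
config key and never silently substituted for a successful scan.

## LBNN: location-based acceptance

LBNN replaces the global two-stage neighbor search with cluster-local
geometry. At fit time the target data are KMOR-clustered (outlier-cluster
members dropped — they are by construction unrepresentative reference
material). For a test point and each cluster $c$ in index order:

1. the **reference point** $P_c$ is the test point's nearest member of $c$,
   at distance $d_c$;
2. $L_c$ collects the distances from $P_c$ to the *other* members of $c$
   (the reference itself excluded — its self-distance is not part of the
   local scale);
3. the point is accepted the first time $d_c$ falls strictly below the
   $Q$-th percentile of $L_c$, and rejected if no cluster accepts.

The percentile is the linear-interpolation order-statistic definition
(rank $Q(m-1)$), so $Q = 0$ demands beating the reference's nearest
in-cluster distance and $Q = 1$ only its farthest. The acceptance set is
monotone in $Q$ by construction. Per-member thresholds are precomputed at
fit time, so classification costs one distance pass over the training
members per test point, within the two-pass bound the decision rule
implies.

Because the hard rule yields no ranking, `lbnn_score()` defines the
continuous score $\min_c d_c / \mathrm{thr}_c$ (with a zero threshold
scoring `Inf`): scores below 1 reproduce the hard decisions exactly, and
the score feeds ROC/AUC computations. Singleton clusters have an empty
$L$; their member is merged into the cluster with the nearest center at
fit time. $Q$ has no canonical value; the default 0.9 accepts anything
closer to its reference than the reference's 90th-percentile cluster mate,
a loose-but-not-maximal choice consistent with the method's bias toward
specificity, and it is an explicit config key (`Q`) everywhere.

## Evaluation

The positive class is always the minority class, so *recall* is
minority-class sensitivity and *specificity* is majority-class acceptance.
G-means is $\sqrt{\text{recall} \times \text{specificity}}$ — with the
square root: recomputing the published LBNN table cells (recall 0.989,
specificity 0.880 giving 0.932; 0.861 and 0.876 giving 0.868) confirms
both the square root and that those tables truncate, rather than round, to
three decimals. `truncate_decimals()` exists for exactly that comparison;
internally nothing is ever rounded. AUC is the rank (Mann–Whitney)
statistic with ties counted 0.5. Metrics with zero denominators are `NA`,
serialized as JSON `null`, and excluded (with counts) from aggregation —
never silently propagated as `NaN`.

The harness (`run_ocnn_experiment()`, `run_lbnn_experiment()`,
`run_baselines()`) repeats a stratified outer split (default 5 folds,
10 rounds; stratification because minority counts as low as 15 make
unstratified folds degenerate), trains one-class methods on the fold's
negative rows only, tunes on proxies where the variant calls for it, and
pools per-fold metrics into mean and sample standard deviation. Folds
without positives are skipped with a warning and counted. Features are
standardized once per fold with target-class training statistics
(population SD, constant features pinned to scale 1), so every estimator
inside a fold shares one metric; the baselines (one-class SVM with
$\nu = 0.5$ and kernel coefficient $1/d$, logistic regression, RBF-SVM,
random forest) are thin wrappers over `e1071`, `stats::glm` and
`randomForest` under the identical protocol — wrapped, not reimplemented.

## The synthetic generator

All tests draw from one seeded generator (`generate_synthetic()`): target
clusters are isotropic Gaussians on a regular simplex, planted outliers
sit at a fixed radius from their cluster center in a random direction, and
the minority class is a Gaussian displaced from the center-of-centers
along a fixed direction orthogonal to the span of the centers. Three named
presets define the constructions used throughout: `blob_with_outliers`
(100 target points, 5% planted outliers at 10 sd — the proxy-tuning
construction), `two_blobs` (two clusters 50 sd apart — cluster recovery),
and `separable` (250 target points in two clusters 10 sd apart plus 50
minority points offset 10 sd — the end-to-end construction).

The presets use 2 features. The margins above are stated per coordinate,
and distances grow like $\sigma\sqrt{d}$, so the same "10 sd" margin that
is decisively separable in 2 dimensions stops being so in 8; low dimension
keeps the constructions both separable and hand-checkable. The test suite
runs these at modest sizes (n of a few hundred, grids to $10 \times 10$,
100-instance property sweeps), which completes in well under a minute per
module.

What passing these tests shows — and does not. The generator produces
isotropic, well-separated, noise-free classes; real medical tables have
correlated mixed-scale features, overlapping classes, and label noise.
Green tests certify the *mechanics* (scores match brute-force oracles,
objectives descend, decisions equal their score formulation, the harness
never leaks a positive row into a one-class fit), not that any method will
reach a particular G-means on hospital data.

## Known limitations

* Exact, naive neighbor search only; no tree or approximate backends, and
  only the Euclidean metric is exercised.
* KMOR's minimum-objective $k$-selection is ill-posed without a bounded
  candidate list (the objective decreases in $k$); the package requires
  the list and reports the curve.
* Proxy-outlier tuning inherits the tail-rejection bias discussed above;
  on clean data it trades specificity for nothing.
* Every model retrains from scratch per fold; there is no incremental or
  online update path.
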
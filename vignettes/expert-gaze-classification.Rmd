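---
title: "Methods: classifying art expertise from fixation patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying art expertise from fixation patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazexpert)
```

## The problem

When people view a painting, their gaze does not wander uniformly: it
returns to a handful of regions — faces, hands, compositional anchors —
that carry most of the pictorial information. Art experts and laymen
differ subtly in *how* they distribute fixations over such regions of
interest (ROIs): in which regions they fixate, how often, and for how
long. `gazexpert` implements a complete pipeline that turns a table of
fixations (subject, group, image, x, y, duration) into a per-subject
classification as `expert` or `layman`, together with the statistical
reporting needed to understand which regions drive the separation.

## The model

### ROI discovery

ROIs are components of a bivariate Gaussian mixture over fixation
positions on one image,

$$f(x) = \sum_{k=1}^{K} \pi_k \, \phi(x;\, \mu_k, R_k),$$

with weights $\pi_k$, centres $\mu_k$ (pixels) and full 2×2 covariances
$R_k$ (so ROIs are arbitrary ellipses). The model is fitted by
expectation–maximization: the E-step computes responsibilities
$p_{ik} = \pi_k \phi(x_i;\Theta_k) / \sum_j \pi_j \phi(x_i;\Theta_j)$ in
log-space; the M-step re-estimates $\pi_k, \mu_k, R_k$ by
responsibility-weighted moments. The log-likelihood is non-decreasing
across iterations — a property the test suite checks on every run.

Fixations are pooled over *all* subjects of both groups when fitting, so
the ROI set is common to everyone; the per-fold "strict" mode described
below exists because this pooling technically lets test subjects
influence the ROI definition.

The number of ROIs is chosen by the Bayesian information criterion,
$\mathrm{BIC} = -2\ln L + m \ln N$ with $m = 6K - 1$ free parameters
(minimized), swept over a default range $K = 2,\dots,20$.

A fixation is assigned to the cluster maximizing $p_{ik}/p_k$, where
$p_k = \sum_i p_{ik}$ is the cluster's responsibility mass
(`rule = "paper_ratio"`). This mass-normalized rule favours small
clusters relative to the plain posterior; because it is nonstandard, the
conventional MAP rule (`rule = "map"`) is also provided. When all
cluster masses are equal the two coincide.

### Numerical choices

* **Initialization.** EM is sensitive to its starting point. The first
  restart is deterministic: Ward agglomeration on a (deterministic)
  subsample seeds the means, a short Lloyd k-means pass refines them,
  and each component starts from its hard partition's local moments.
  Remaining restarts use k-means++ seeding. Starting every component at
  the *global* covariance — an obvious alternative — makes the initial
  responsibilities nearly uniform and, empirically, strands EM in
  merged/split local optima often enough that BIC then mis-selects K by
  one or two; the agglomerative start removed this failure mode
  entirely in our planted-model checks.
* **Regularization.** Each covariance carries a diagonal floor
  $\varepsilon = 10^{-6}\,\mathrm{tr}(\Sigma_{\text{global}})/2$
  (pixels²) so near-empty clusters cannot collapse to singular
  matrices; a cluster whose responsibility mass vanishes aborts the
  restart, and the best non-degenerate restart wins.
* **Convergence.** Absolute log-likelihood change below `tol` (default
  $10^{-6}$) or 500 iterations. For BIC sweeps a looser `tol` of
  $10^{-4}$ is adequate: BIC differences between neighbouring K are two
  orders of magnitude larger than the likelihood tail.
* **Restarts.** Default 10. The acceptance runs use 2 because the
  deterministic agglomerative restart already lands in the right basin
  on separated data, and the sweep budget is one CPU.

### Features and normalization

For each subject and cluster $k$: $l_k$, the number of the subject's
fixations in the cluster, and $t_k$, their mean duration in ms (0 if the
subject never fixated the cluster — a convention that keeps matrices
complete; the alternative, NA plus imputation, would inject information
across subjects). That yields $2K$ features per subject per image.

Four z-score schemes $z = (x - m)/\sigma$ (sample SD, $\sigma = 0 \to
z = 0$) differ in the pooling set:

| tag | pooling set for $m, \sigma$ |
|-----|------------------------------|
| Z0  | none (raw) |
| Z1  | per feature column, across subjects |
| Z2  | per subject, across clusters **and** images |
| Z3  | per subject, across clusters, within one image |

Z2/Z3 pool count features and duration features *separately*: they live
on incommensurable scales (counts vs milliseconds), and pooling them
together would make each subject's z-scores mostly encode the
count/duration scale gap rather than individual differences. This
per-type pooling is a design choice the source material left open.

### Selection and classification

Two selectors: a filter (rank features by absolute pooled two-sample
t-statistic between the groups) and a wrapper (sequential forward
selection, greedily adding the feature that maximizes
leave-one-subject-out accuracy of the working set; ties break toward
the lower feature index, making runs fully deterministic).

Classifiers: k-NN (Euclidean, default $k = 3$) and soft-margin SVMs with
linear, RBF and sigmoid ($\tanh(\gamma x\cdot x' + c_0)$) kernels. The
SVM dual is solved by maximal-violating-pair SMO to KKT tolerance
$10^{-6}$; since the sigmoid kernel is not positive semi-definite for
all parameters, the two-variable step floors its curvature at a small
positive value and the update count is capped, so the solver terminates
on indefinite kernels too. Kernel hyperparameters were not reported in
the study this mirrors, so defaults are the reproducible conventions
$C = 1$, $\gamma = 1/(p\,\mathrm{Var}(x))$ ("auto"), $c_0 = 0$ — exact
replication of the original accuracies is out of reach regardless,
because the recordings were never released.

Evaluation is leave-one-subject-out: each subject is the test fold
once; accuracy is (TP+TN)/N. Two regimes:

* `replicate_paper` (default): normalization and feature selection are
  computed once on all subjects before the loop, mirroring the original
  single-pass design. This is optimistically biased — the held-out
  subject influenced the selected features — and the documentation says
  so prominently.
* `strict`: per fold, Z1 statistics come from the training subjects
  only and the selector is re-run on the training fold (nested CV).
  Z2/Z3 pool within-subject only and carry no cross-subject leakage.

Whether the original analysis selected features inside or outside the
loop is not stated; both are provided and the default replicates.

## The synthetic cohort generator

`default_spec()` encodes the reference study design: 23 experts and 21
laymen, one image, 14 planted elliptical ROIs on a jittered 4×4 grid
(two corners dropped) inside a 1920×1200 frame. Per cluster and group,
fixation counts are Poisson with the per-cluster rates of the shipped
reference table (`reference_cluster_stats()`); durations are lognormal
(fixation durations are right-skewed) moment-matched to the reference
means with SD = 40% of the mean — the reference reports no dispersions,
so 40% is a convention chosen once, in line with typical fixation-
duration variability. The two groups differ **only** where the original
cohort showed its clearest differences: cluster 1 counts (13.6 vs 18.3
per viewing) and cluster 10 mean durations (119.3 vs 128.1 ms).
`amplify_effects(spec, f)` scales those group gaps about their mean
(`f = 0` is the null cohort; `f = 3` the power setting used in the
acceptance checks).

ROI spreads (SDs ≈ 20–42 px) are set so that centre spacing is at least
~6 standard deviations. This is deliberate: the recovery criteria
presuppose separated clusters (≥ 4σ), and with much wider ROIs the
rarest planted clusters (≈ 22 fixations, 0.9% of mass) carry less
log-likelihood than one component's BIC penalty, making K
unidentifiable *in principle* — no fitting improvement can recover it.
The chosen world keeps every stated criterion meaningful.

What a green test does establish: the estimator recovers planted
structure (K, means, weights) and the classifier behaves at chance on
null cohorts and with high accuracy on amplified ones. What it does not
establish: performance on real gaze data, whose ROIs are not Gaussian,
whose fixation counts are overdispersed relative to Poisson, and whose
subjects have idiosyncratic scanpaths correlated across clusters — none
of which the generator emulates.

## Known limitations

* The BIC scale printed in the original study (≈ 3.6×10⁻⁵ at the
  optimum) is inconsistent with $-2\ln L + m\ln N$ and is not
  reproduced; only the argmin behaviour is matched.
* The `paper_ratio` assignment rule can assign a fixation to a distant
  small cluster when masses are very unequal; `map` is the safe choice
  outside replication work.
* The sigmoid-kernel SVM is a heuristic for non-PSD parameters; its
  solutions are stationary points, not guaranteed global optima.
* Durations are modelled independently of positions within a cluster;
  real fixation durations correlate with content.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(
  input = "synthetic", k_range = c(2, 20),
  selector = list(method = "sfs", n = 5),
  classifiers = list(classifier_spec("svm", kernel = "sigmoid")),
  seed = 1)
man <- run_pipeline(cfg, "run1")
man$grids[["svm-sigmoid"]]
man$summary$per_normalization
```

Every number the package's documentation quotes is computed by the test
suite or by `scripts/acceptance.R`; nothing above is asserted from
memory of a run that the shipped code cannot repeat.
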
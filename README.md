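# gazexpert

Can you tell an art expert from a layman by *how they look* at a
painting? `gazexpert` is an R package for exactly this question: it
takes tables of eye-tracking fixations (subject, group, image, x/y in
pixels, duration in ms) recorded while people view paintings, and runs a
complete, reproducible classification pipeline:

1. **ROI discovery** — fixation positions of all viewers of an image are
   modelled as a bivariate Gaussian mixture
   `f(x) = Σ_k π_k φ(x; μ_k, R_k)`, fitted by EM; the number of regions
   of interest K is chosen by BIC (`−2 ln L + (6K−1) ln N`, minimized).
2. **Features** — per subject and ROI: `l_k`, the fixation count, and
   `t_k`, the mean fixation duration (ms), i.e. 2K features per image;
   optional z-score normalizations `Z1` (per feature, across subjects),
   `Z2` (per subject, across clusters and images) and `Z3` (per subject,
   within image).
3. **Selection** — rank by two-sample t-statistic, or sequential forward
   selection (SFS) driven by cross-validated accuracy.
4. **Classification** — k-NN (Euclidean) or soft-margin SVM (linear,
   RBF, sigmoid/"MLP" kernels; SMO solver written for this package,
   robust to the sigmoid kernel's indefiniteness), evaluated by
   leave-one-subject-out cross-validation (accuracy = (TP+TN)/N).
5. **Reporting** — per-cluster group statistics (means, t, p; t-sums and
   best-cluster p per image) and picture × normalization accuracy grids
   with row/column/grand means.

Because the original recordings of the study this mirrors (23 experts,
21 laymen, five paintings, 15 s viewing) were never released, the
package ships (a) the study's printed result tables as plain CSVs
(`reference_accuracy_grids()`, `reference_group_summary()`,
`reference_cluster_stats()`), used as worked-example inputs for the
aggregation operations, and (b) a **synthetic cohort generator**
(`default_spec()`, `generate_cohort()`) that plants the published
per-cluster rates and duration means as ground truth, so every
estimator can be tested against a known world.

## Worked example

One call runs the whole grid on a synthetic cohort with 3×-amplified
group effects (the planted differences: experts make 13.6 vs 18.3
fixations in cluster 1, and fixate 119.3 vs 128.1 ms in cluster 10):

```r
library(gazexpert)
cfg <- pipeline_config(
  input = "synthetic", k_range = c(2, 20),
  em = list(tol = 1e-4, max_iter = 500L, n_restarts = 2L),
  selector = list(method = "sfs", n = 5),
  classifiers = list(classifier_spec("svm", kernel = "sigmoid")),
  seed = 1)
cfg$spec <- amplify_effects(default_spec(seed = 1), 3)
man <- run_pipeline(cfg, "run1")

man$grids[["svm-sigmoid"]]
#>        Z0 Z1  Z2  Z3 mean
#> P2   0.77  1 0.8 0.8 0.84
#> mean 0.77  1 0.8 0.8 0.84

man$summary$t_sums
#>   picture t_sum_count t_sum_duration optimal_k best_p_count best_p_duration
#> 1      P2    20.89236       18.86985        14 1.626073e-12     0.007428031
#> 2    mean    20.89236       18.86985        14 1.626073e-12     0.007428031
```

Reading the output: BIC recovered the planted `optimal_k = 14`; the
accuracy row is leave-one-subject-out accuracy per normalization (1.00
under Z1 here — the amplified count effect is essentially separable);
`best_p_count ≈ 2e-12` flags the planted cluster-1 count difference.
`run1/` holds every intermediate artifact (fixations, model JSON, BIC
trace, ellipses, feature CSVs, per-cell CV results, rendered grids, a
manifest with md5 hashes); rerunning with the same seed reproduces the
numbers exactly.

On **null** cohorts (`null_spec()`, group effects removed) the same
pipeline sits at chance: mean LOOCV accuracy 0.47–0.50 across seeds —
see `scripts/acceptance.R` output below.

A command-line front end with subcommands
`validate / describe / simulate / cluster / features / classify / run`
lives at `inst/cli/gazexpert.R`:

```sh
Rscript inst/cli/gazexpert.R simulate --seed 2 --out cohort/
Rscript inst/cli/gazexpert.R cluster --fixations cohort/fixations.csv \
        --image P2 --kmin 2 --kmax 20 --seed 2 --out model.json
#> best K = 14 (BIC 63579.47); model written to model.json
```

## Documentation

The methods vignette (`vignettes/expert-gaze-classification.Rmd`)
explains the model and its assumptions, every tunable parameter with
units and defaults, what the synthetic generator does and does not
emulate, the numerical choices (initialization, regularization,
tie-breaks, the non-PSD sigmoid kernel), and known limitations.
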
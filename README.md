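# mselm

Multisource distribution-adaptive feature learning with a regularized
extreme learning machine, for binary image classification under domain
shift.

The package is aimed at the situation that arises in medical-imaging
classification — e.g. separating gastric cancer (GC) from primary gastric
lymphoma (PGL) on venous-phase CT — where labeled target images are scarce
but several related cohorts (pathology whole-slide images, CT from another
contrast phase or another hospital) exist in quantity. It provides the
full pipeline as reusable, tested R functions: synthetic multi-domain data
generation, an adaptively weighted divergence between each source and the
target, a small multisource transfer network with an ensemble of
sub-predictors, deep-feature export, mRMR feature selection, an extreme
learning machine with three output-weight solvers, and ROC/confusion-matrix
evaluation.

## The method

For each source–target pair the divergence between feature distributions is
a Wasserstein-weighted combination of marginal and class-conditional
maximum mean discrepancy. With Gaussian-kernel MMD
`M_H` estimated by its V-statistic and per-class terms `M_H^(l)`,

    M_MMD = (1 - mu) * M_H + mu * (M_H^(0) + M_H^(1)),
    mu    = (W_0 + W_1) / (W_g + W_0 + W_1),

where `W_g` is the exact empirical Wasserstein-1 distance between the two
sets (solved as a min-cost-flow transport problem) and `W_l` the per-class
distances computed on domain-mean-centered features. `mu -> 0` flags a
dominating marginal (global) discrepancy, `mu -> 1` a dominating
class-conditional one. A feature-extraction network — one shared trunk,
one specific extractor and one softmax sub-predictor per source — is
trained to minimize

    l_total = alpha * mean_j M_MMD^(j) + cross-entropy(ensemble, target labels),

with `alpha = max(0, 2 exp(-theta * progress) - 1)`, `theta = 10`.
Pooled deep features are exported, the top fraction (10% by default) is
kept by minimum-redundancy maximum-relevance selection, and an extreme
learning machine classifies them; its output weights solve the printed
regularized closed form `phi = (G'G + (1/beta) I)^{-1} G'Y` with
`beta = 0.05` by default (an L1 coordinate-descent solver and the plain
pseudoinverse are also provided). Metrics are Sen/Spe/Acc/Pre/F1 plus
trapezoidal ROC/AUC.

## Worked example

Three synthetic source domains (64 images per class each), a scarce
labeled target training set (8 per class), and a held-out target cohort:

```r
library(mselm)

domains <- gen_preset_image_domains("mixed", n_per_class = 64, image_size = 32,
                                    n_sources = 3, n_target_per_class = 8,
                                    noise_sd = 0.3, seed = 1)
holdout <- gen_preset_image_domains("mixed", n_per_class = 150, image_size = 32,
                                    n_sources = 1, n_target_per_class = 150,
                                    noise_sd = 0.3, seed = 5001)[[1]]

fit <- mselm(domains[-1], domains[[1]],
             backbone = backbone_spec(channels = c(8L, 16L)),
             specific = specific_spec(c(8L, 8L, 4L)),
             config = training_config(batch_size = 16, iterations = 250),
             mrmr_fraction = 0.25, hidden = 200, seed = 1)
summary(fit)
#> Training: 250 iterations; final l_mmd 1.0194, l_task 0.6367, l_total 0.6367
#> Mean adaptation factor mu per source (training average):
#>   S1: 0.556
#>   S2: 0.694
#>   S3: 0.484
#> Features: 9 selected of 36; ELM solver: ridge

evaluate_mselm(fit, holdout)
#> Confusion: TP 120  FN 30  TN 100  FP 50
#> Sen 0.800  Spe 0.667  Acc 0.733  Pre 0.706  F1 0.750
#> AUC 0.832
```

The per-source `mu` averages say how each pair's divergence was split
during training: values above 0.5 (here S2) mean the class-conditional
discrepancy dominated that pair's alignment, values near 0.5 (S3) mean
marginal and conditional discrepancy weighed about equally. The
held-out report shows the ELM pipeline classifying a 300-image target
cohort it never saw, from 16 labeled target images.

The same run is available as a one-call pipeline that writes its resolved
configuration, training history, feature tables, selection, scores and
report to a directory:

```r
res <- run_pipeline(pipeline_config(seed = 1), out_dir = "run1")
```

and as a command-line tool
(`inst/scripts/mselm-cli.R`, subcommands `simulate`, `divergence`,
`train-extract`, `select`, `fit-elm`, `evaluate`, `run`).

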
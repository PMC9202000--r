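# axunet

Boundary-aware encoder–decoder segmentation of small soft-tissue
targets in CT, with downstream GLCM radiomics — an R implementation of
the AX-Unet family of ideas, built for a task where the organ of
interest (the pancreas) occupies well under 1.5% of a 2D slice, has
near-background contrast, and hides most of its clinically relevant
error on a blurry boundary.

The package is aimed at methodologists who want a fully inspectable,
dependency-light reference implementation: the network, its backward
pass and the optimizer are all implemented here (single-precision
RcppArmadillo, im2col + GEMM), every loss and metric is tested against
brute-force oracles, and a seeded phantom generator makes the entire
pipeline runnable and testable with no data download.

## What is implemented

**Architecture** (`model_config()`, `build_model()`): a U-shaped
encoder–decoder with residual links; in the `ax_unet` variant the first
convolution of every double-convolution block (except the network's
first layer) is depth-wise separable — a 1×1 pointwise map from M to N
channels followed by one 3×3×1 kernel per channel, so the parameter
count drops from `3·3·M·N` to `3·3·M + 1·1·M·N`. The bottleneck is a
modified atrous spatial pyramid pooling module: a 1×1 branch, 3×3
atrous branches at rates (2, 4, 6), and a global-average-pool branch,
fused by 1×1 convolution. The decoder mirrors the encoder with grouped
2×2 transposed-convolution upsampling and skip concatenation, ending in
a 1×1 convolution to two class maps.

**Hybrid loss** (`hybrid_loss()` and components): with foreground
probability `p` and binary target `y`,

    L = w1·CAL + w2·Focal + w3·GDL,        (w1, w2, w3) = (0.6, 0.2, 0.2)

where GDL is the generalized Dice loss with class weights
`w_j = 1/(Σ_i y_ij)²`, Focal is `−α(1−p)^γ log p` / `−(1−α)p^γ log(1−p)`
with α = 0.25, γ = 2, and CAL compares Sobel edge maps of prediction
and target pixel-wise (entropy-referenced cross-entropy; an MS-SSIM
criterion is available). All components return analytic gradients and
are finite-difference checked.

**Metrics** (`dice()`, `jaccard()`, `precision_recall()`,
`hausdorff()`): pixel-count overlap metrics plus the symmetric max–min
Euclidean Hausdorff distance on 4-connectivity boundary point sets.

**Phantoms** (`phantom_spec()`, `make_phantom()`, `make_cohort()`,
`make_volume()`): seeded CT-like images — a dark noisy background and
one small, elongated, smooth-edged blob — with optional tumor-like
intra-blob heterogeneity for two-group cohort studies.

**Training pipeline** (`train_model()`, `predict()`,
`kfold_split()`, preprocessing): RMSProp on the hybrid loss, fixed-step
learning-rate decay, subject-disjoint k-fold splitting, min-max
normalization and 2.2× contrast enhancement shared between training
and inference, PNG/NIfTI I/O, and a CLI (`inst/cli/axunet.R`).

**Radiomics + statistics** (`compute_glcm()`, `texture_features()`,
`pearson_screen()`, `normality_test()`, `mann_whitney()`,
`cohort_report()`): ten GLCM texture features (entropy in nats, energy,
homogeneity, dissimilarity, edge sharpness, contrast, GLCM contrast,
GLCM marginal mean/sd, gray mean), Pearson correlation screening,
Shapiro–Wilk normality per group, and an exact-enumeration Mann–Whitney
U test with tie-corrected normal approximation for larger groups.

## Worked example

```r
library(axunet)

# 3x3-kernel accounting: the all-normal-convolution topology
count_3x3_kernels(model_config(variant = "baseline_unet"))
#> <axunet_kernel_report> variant=baseline_unet convolutions=16 total 3x3 kernels=1,040,768
count_3x3_kernels(model_config())          # depth-wise separable variant
#> <axunet_kernel_report> variant=ax_unet convolutions=16 total 3x3 kernels=522,432

# train a small network on seeded phantoms and evaluate held-out slices
phs  <- lapply(1:60, function(i) make_phantom(phantom_spec(seed = i, size = c(64L, 64L))))
imgs <- lapply(phs, function(p) preprocess_slice(p$image))
msks <- lapply(phs, function(p) p$mask)
fit  <- train_model(build_model(model_config(base_width = 16L, depth = 3L, seed = 1L)),
                    imgs[1:45], msks[1:45],
                    train_config(batch_size = 2L, epochs = 10L, seed = 1L))
tail(fit$history[, c("epoch", "loss", "cal", "focal", "gdl")], 3)
#>   epoch   loss     cal    focal   gdl
#> 1     8 0.0837 0.00481 0.000717 0.403
#> 2     9 0.0773 0.00375 0.000668 0.374
#> 3    10 0.0730 0.00302 0.000618 0.355

pred <- lapply(46:60, function(i) predict(fit$model, phs[[i]]$image))
glance(evaluate_masks(pred, msks[46:60]))[, c("dice_mean", "hausdorff_mean")]
#>   dice_mean hausdorff_mean
#> 1     0.946              1
```

A held-out Dice of 0.946 and a mean boundary Hausdorff distance of
1 pixel: after ten epochs the small network recovers the blob almost
exactly, with boundary error at the resolution limit.

```r
# two-group radiomics on a synthetic cohort (13 normal vs 31 tumor-like)
rep_ <- cohort_report(make_cohort(13, 31, phantom_spec(), seed = 42))
tidy(rep_)[, c("feature", "U", "p", "significant")]
#>   feature       U           p significant
#> 1 entropy       1 0.000000268 TRUE
#> 2 gray_mean   228 0.504       FALSE
#> 3 glcm_mean   403 0.000000234 TRUE
#> 4 glcm_std    371 0.0000138   TRUE
```

Six redundant features are screened out by Pearson correlation
(|r| ≥ 0.9); among the retained ones, intra-ROI gray-level entropy
separates the tumor-like group sharply (Mann–Whitney U = 1,
p ≈ 2.7e-7), which is the screening signal the cohort pipeline is
designed to surface.

See `vignettes/axunet-methods.Rmd` for the full model description,
parameter choices, numerical conventions and known limitations.

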
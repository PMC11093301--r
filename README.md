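# fchybrid

Hybrid CNN–SVM classification of autism spectrum disorder from
resting-state functional connectomes fused with Social Responsiveness
Scale (SRS) scores — with weight-based and Shapley-based
interpretability, and a synthetic cohort generator with planted ground
truth for end-to-end validation.

## Who this is for

Researchers working with ROI-level resting-state fMRI (e.g. AAL-116
time series, already band-pass filtered to 0.01–0.08 Hz) who want to

* build **static FC** (Pearson correlation matrices) and **dynamic
  FC** (Morlet wavelet coherence per ROI pair, reduced over time by
  PCA into an R×R×Q tensor),
* extract deep features from both connectomes with **row/column-kernel
  CNNs** and sigmoid attention,
* fuse them with the five SRS subscales in a **linear-kernel SVM**
  under stratified 10-fold cross-validation, and
* ask *which regions*, *which frequency bands*, and *which feature
  blocks* drive the classification.

## The model

Static connectivity between regions X and Y is the Pearson coefficient

    R(X,Y) = Σ(xᵢ−x̄)(yᵢ−ȳ) / √(Σ(xᵢ−x̄)² Σ(yᵢ−ȳ)²).

Dynamic connectivity is wavelet coherence: with W_x(s,τ) the Morlet
CWT (ω₀ = 6) of signal x at Q = 40 scales spanning 0.01–0.08 Hz,

    R_xy = |S(W_x W_y*)|² / ( S(|W_x|²) · S(|W_y|²) ),

where S is a scale-adaptive moving average in time followed by a
boxcar over scales. Each pair's Q×T coherence map is reduced over
time: demean, eigendecompose the scale covariance, keep components to
99% variance, store the leading eigenvalue-scaled eigenvector — one
Q-vector per pair, one R×R×Q tensor per subject regardless of scan
length.

Each connectome feeds a small CNN whose kernels span whole rows or
columns (32 filters of 1×R → 64 of R×1 → 16 of 1×1, each with batch
norm and LeakyReLU(0.01); the dynamic branch first compresses its Q
channels with a single 1×1 filter), followed by dropout, a sigmoid
attention gate and an auxiliary 2-class head used only for training
(Adam, lr 1e-4, ≤50 epochs, cross-entropy). The attention-gated
16-vectors from both branches are concatenated with the 5 SRS scores
and classified by a linear SVM. Interpretability: region importance =
column sums of |first-layer kernel weights|; band importance =
|channel-compression weights|; block attribution = exact 3-player
Shapley values of the SVM decision function with mean-imputed
baselines.

## Worked example

```r
library(fchybrid)

cfg   <- pipeline_config(n_roi = 8, n_bands = 10, n_folds = 3)
truth <- cohort_truth(n_roi = 8, n_asd = 12, n_tc = 12,
                      planted_pairs = list(c(2, 5)))
cohort  <- simulate_cohort(truth, seed = 11)
records <- compute_connectivity(cohort, cfg)

cv <- cross_validate(records, cfg, seed = 3)
glance(cv)
#> # A tibble: 1 × 9
#>     ACC   SEN   SPE   FPR    FNR Precision    F1 n_folds best_fold
#>   <dbl> <dbl> <dbl> <dbl>  <dbl>     <dbl> <dbl>   <int>     <int>
#> 1 0.875 0.917 0.833 0.167 0.0833     0.867 0.878       3         1
```

The cohort plants a coupled pair (ROIs 2 and 5, shared narrowband
component at 0.04–0.05 Hz, in-band coherence 0.9 for the ASD group vs
0.1 for controls) and an SRS group shift; the cross-validated mean
accuracy (here 0.875 on 24 subjects with per-fold CNN retraining)
shows the planted effects are recoverable. Interpretability on the
fitted bundle:

```r
grid <- frequency_grid(cfg)
ex <- explain_report(cv, records, grid,
                     subjects = cohort$phenotypes$subject_id[1:3])
ex$shapley[1:3, ]
#> # A tibble: 3 × 6
#>   subject_id block     phi phi_abs   f_x f_baseline
#>   <chr>      <chr>   <dbl>   <dbl> <dbl>      <dbl>
#> 1 asd_001    srs     0.379   0.379  1.00    -0.0227
#> 2 asd_001    static  0.372   0.372  1.00    -0.0227
#> 3 asd_001    dynamic 0.272   0.272  1.00    -0.0227
```

For subject `asd_001` the SVM score moves from −0.02 (population
baseline) to +1.00 (confident ASD), and the three feature blocks
contribute comparably — the signed φ values sum exactly to the score
difference (Shapley efficiency). `autoplot(cv)`,
`autoplot(ex$regions_static)` and `autoplot(ex$bands)` plot per-fold
metrics, region rankings and band rankings; `tidy(cv)` returns the
per-fold metrics as a long tibble.

A command-line wrapper (`inst/cli/fchybrid.R`) exposes the same
pipeline as `simulate | fc | train | evaluate | explain` subcommands
over TSV/CSV inputs, a serialized connectivity store, and JSON
metric/report outputs.

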
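---
title: "Hybrid CNN-SVM classification from functional connectomes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid CNN-SVM classification from functional connectomes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Autism spectrum disorder is usually screened behaviourally (for
instance with the Social Responsiveness Scale, SRS, whose five
subscales quantify social awareness, cognition, communication,
motivation and mannerisms) and studied neurally with resting-state
fMRI. `fchybrid` implements a hybrid classifier that fuses both
sources: functional connectivity (FC) matrices computed from ROI time
series feed two small convolutional feature extractors, and the
resulting deep features are concatenated with the five SRS subscale
scores and classified by a linear-kernel support vector machine.
Alongside classification, the package ranks brain regions and
frequency bands by the weights the networks learned, and attributes
each prediction to its three feature blocks with exact Shapley values.

The package consumes ROI time series that are already band-pass
filtered (0.01--0.08 Hz) and atlas-extracted; raw image preprocessing
(slice timing, motion correction, registration, nuisance regression)
is explicitly out of scope.

## Connectivity models

**Static FC.** The Pearson correlation matrix of the ROI columns:
$R(X,Y) = \frac{\sum_i (x_i-\bar x)(y_i - \bar y)}
{\sqrt{\sum_i (x_i-\bar x)^2\sum_i (y_i-\bar y)^2}}$, an $R\times R$
symmetric matrix with unit diagonal. Columns with zero variance are
rejected rather than silently propagated (the denominator would be 0).

**Dynamic FC.** For each ROI pair we compute the Morlet wavelet
coherence. The continuous wavelet transform
$W(s,\tau) = \tfrac{1}{\sqrt s}\int x(t)\,\phi^*\!\big(\tfrac{t-\tau}{s}\big)dt$
is evaluated with the analytic Morlet mother wavelet
($\pi^{-1/4} e^{i\omega_0 t}e^{-t^2/2}$, $\omega_0 = 6$ by default,
the standard admissible choice balancing time and frequency
resolution) by frequency-domain multiplication with zero padding to
the next power of two. The analysis band 0.01--0.08 Hz is divided
into $Q = 40$ contiguous segments, linearly spaced by default (log
spacing is available); segment midpoints map to scales through
$f = \omega_0 / (2\pi s\,\mathrm{TR})$.

The coherence of a pair is
$R_{xy} = |S(W_x W_y^*)|^2 \,/\, \big(S(|W_x|^2)\,S(|W_y|^2)\big)$,
where $S$ is a separable moving average: a boxcar in time whose width
grows with scale ($\max(3, \mathrm{round}(0.6\,s))$ samples,
reflective edges) followed by a 3-bin boxcar over scales. Two
identities pin the implementation down:

* without smoothing, $|W_xW_y^*|^2 = |W_x|^2|W_y|^2$ pointwise, so the
  coherence is identically 1 for *any* pair — the smoother is what
  makes coherence informative, and this degeneracy is kept as a
  regression test;
* because the same positive-weight average is applied to numerator
  and denominator, Cauchy–Schwarz keeps every cell in $[0,1]$ (up to
  float error $\le 10^{-9}$, which is clipped).

The smoothing window sizes are declared package defaults: the moving
average is standard for wavelet coherence but no canonical widths
exist; 0.6 of a scale in time and 3 scale bins sit in the usual range
and preserve the identities above. No cone-of-influence masking is
applied; edge effects are mitigated only by the reflective padding of
the smoother.

**Temporal PCA.** Coherence maps are $Q\times T$ with $T$ varying
across sites and subjects, so they are reduced over time: remove the
mean time column from $WC$, form
$C = \widehat{WC}\,\widehat{WC}^{\top}/T$, eigendecompose, keep the
smallest $k$ whose cumulative eigenvalue fraction reaches 0.99, and
project $XP = C P = P\Lambda$ (a $Q\times k$ matrix whose columns are
eigenvectors scaled by their eigenvalues; with $X = C$ this is the
only dimensionally consistent reading of the projection step).
Eigenvector signs are arbitrary, so they are fixed deterministically:
each component's entry sum is made non-negative, ties broken by the
first nonzero entry. Only the first component populates the
$R\times R\times Q$ tensor even when $k > 1$ is needed — the tensor
shape must stay fixed across subjects — and a warning lists the pairs
concerned. On noisy desk-scale data this warning is routine (the 99%
rule often needs several components); the recorded `k_used` and
`variance_retained` matrices keep the information auditable. The
diagonal is zero by construction: a self-coherence map is constant 1
and demeaning annihilates it.

## CNN feature extractors

A connectome is not a natural image: a $3\times 3$ patch has no
meaning, but a whole row (or column) is one region's connectivity
profile. Both branches therefore use row/column kernels:

* static branch: $R\times R\times 1$ input → 32 filters of $1\times R$
  → 64 of $R\times 1$ → 16 of $1\times 1$, each convolution followed
  by batch normalisation and LeakyReLU(0.01); then dropout (rate 0.5),
  an attention block (dense 16→8, ReLU, dense 8→16, sigmoid) whose
  output gates the 16-vector elementwise, and an auxiliary 2-class
  softmax head used only to provide a training signal;
* dynamic branch: identical, with a leading channel-compression
  convolution (1 filter, $1\times 1$ kernel across the $Q = 40$
  frequency channels) collapsing the tensor to one map.

Because every kernel spans a full row or column, each convolution is
exactly a matrix product, and the engine implements it that way in
plain, seeded R — training (Adam, learning rate $10^{-4}$, cross
entropy, at most 50 epochs) is deterministic given the seed. The
extracted per-subject feature is the attention-gated 16-vector, read
in inference mode (dropout off, batch norm on running statistics).
Batch-norm epsilon ($10^{-5}$) and momentum (0.1) follow common
framework defaults. LeakyReLU is used everywhere except the attention
hidden layer, which is a plain ReLU. Convolutions are valid, stride 1,
with biases; dropout sits between the conv stack and the attention
block.

Two training defaults deserve explanation:

* **Batch size 8.** The optimisation budget is fixed (≤50 epochs at
  learning rate $10^{-4}$). On a multi-hundred-subject cohort at
  batch 32 that budget corresponds to roughly a thousand optimiser
  steps; a 200-subject desk cohort at batch 32 would get only ~300.
  Since Adam's per-step movement is capped near the learning rate,
  too few steps leave the early layers essentially at their random
  initialisation. Batch 8 restores the intended step count at desk
  scale.
* **First-layer initialisation at a tenth of the fan-in scale.** The
  channel-compression weights and the first $1\times R$ kernel bank
  are exactly the weights later read out for interpretability (band
  and region rankings, as sums of absolute weights). Batch
  normalisation directly after each of these layers makes the network
  *function* invariant to their overall scale, so the initial
  magnitude is a free parameter — but the rankings are not: with a
  full-scale init the total weight movement achievable in the budget
  (~0.1 in absolute value) cannot escape the random init spread, and
  rankings would reflect the draw, not the data. Scaling the init by
  0.1 lets learned structure dominate. Other layers use the standard
  fan-in-scaled uniform init.

## Fusion, evaluation, interpretability

Per cross-validation fold (stratified, 10-fold by default, seeded),
both branches are trained on the training subjects only; features are
extracted for everyone; each of the 37 feature columns (5 SRS + 16
static-deep + 16 dynamic-deep) is z-scored with training-fold
statistics (SVMs are scale-sensitive, and raw SRS scores would dwarf
the deep features); a linear-kernel SVM (C = 1 by default) is fit and
scores the held-out fold. Nothing from a validation subject — label
or feature — touches any training step, and a test asserts that
corrupting validation labels leaves every fitted object bit-identical.
Baselines (MLP with hidden layers 64 and 16, random forest with 100
trees, logistic regression thresholded at 0.5 with ties classified
positive) run on the same z-scored features. Metrics are exact
formula evaluations from the confusion counts with ASD as the
positive class; a zero denominator yields `NA`, never 0.

Interpretability has three read-outs. Region importance is the
column-wise sum of absolute weights of the $32\times R$ first-layer
kernel bank (for the dynamic branch, the conv after compression —
the same bank); ties rank by lower index. Band importance is the
absolute channel-compression weight per frequency segment. Block
attribution enumerates all $2^3$ coalitions of the three feature
blocks exactly; a block absent from a coalition is replaced by the
training-set feature means (the baseline choice; the coherence of
this convention is what the efficiency axiom checks), and the value
function is the SVM's real-valued decision score, not the hard label
(Shapley values of a step function would be degenerate).

## The synthetic cohort

Real multi-site autism cohorts with SRS phenotypes are access
restricted, so validation uses a generator with planted, recoverable
ground truth. Each ROI signal is unit-variance Gaussian noise
confined to 0.01--0.08 Hz by Fourier masking. A coupled pair shares a
latent narrowband component restricted to the planted band
(0.04--0.05 Hz by default), mixed with variance fraction $w$; writing
$B_p$ and $B_t$ for the planted and total bandwidths, the expected
in-band coherence is $\rho^2$ with
$\rho = (w/B_p)\,/\,(w/B_p + (1-w)/B_t)$, and the generator inverts
this closed form to hit a requested coherence target (0.9 for the
ASD group, 0.1 for controls by default — a strong, documented
contrast). SRS subscales are Gaussian on a T-score-like scale
(control mean 45, SD 10) with a standardised group difference of 3,
the separation a screening instrument is designed to achieve; at this
setting the SRS block alone nearly separates the groups, which mirrors
the instrument's real behaviour and makes the planted-connectivity
recovery tests, not the headline accuracy, the demanding part.

The reference cohort is desk-scale: 20 ROIs, 150 time points at
TR = 2 s, 100 subjects per group, all 40 frequency segments retained.
These sizes keep the full pipeline (connectivity, per-fold CNN
retraining, 10-fold CV, recovery simulations) in the minutes range
while preserving every tensor shape structurally. What the generator
does *not* emulate: hemodynamic autocorrelation, site and scanner
effects, head motion, age/sex structure, label noise, and realistic
(weak, distributed) connectivity differences. Passing tests therefore
demonstrate mechanical and statistical correctness of the pipeline,
not clinical performance.

## Numerical choices and degenerate inputs

* Frequency-domain CWT with zero padding to the next power of two;
  linearity and the zero signal are exact tests.
* Coherence denominators cannot vanish for non-constant signals with
  a positive smoothing kernel; a zero cell raises an error naming its
  location.
* Constant coherence maps (self-pairs) reduce to a zero projection
  with `k = 1`, `variance_retained = 1` by convention.
* All stochastic stages draw from seeds derived deterministically
  from one master seed (`derive_seed`); reruns are bytewise identical
  including serialized JSON reports.
* SVM decision values are re-oriented so positive always means the
  ASD class regardless of the backend's internal class order.

## Known limitations

* Only the first PCA component enters the dynamic tensor; when the
  99% rule needs more, information is discarded (logged per pair).
* Weight-magnitude band ranking is weakly identified at desk scale:
  when the cohort is so separable that the cross-entropy head
  saturates within a few epochs, the compression weights stop
  receiving consistent gradients (their direction is nearly
  unidentifiable behind the 32-filter bank) and their magnitudes
  remain close to initialisation. The region ranking does not suffer
  from this — the first kernel bank is the primary discriminative
  projection and is reshaped before saturation. The package reports
  measured recovery rates rather than asserting band recovery works.
* The SRS subscale scaling (raw vs T-scores) is not assumed; any
  finite values are accepted and z-scored per training fold.
* No cone-of-influence masking; coherence cells near the record edges
  are biased by the reflective padding, identically across groups.
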
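---
title: "Methods: hyperspectral chemometrics for root authentication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral chemometrics for root authentication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and problem

`rootspec` implements a visible/near-infrared (VIS-NIR) hyperspectral
workflow for authenticating medicinal root material. Three morphological
classes of root are distinguished — tuberous root (the accepted medicinal
material), taproot, and old root — and three marker analytes
(norisoboldine, linderane, lindenenol) are quantified from reflectance
spectra and mapped pixel-wise across the sample surface. A companion
metabolomics screen flags differential features between the classes from
feature-intensity tables.

No instrument data ships with the package. Every stage is exercised on
synthetic data whose generator is itself first-class, tested code; this
vignette records the generative model, the numerical conventions, and the
design choices that were genuinely open.

# The synthetic reflectance model

A sample's relative reflectance at wavelength $\lambda$ is

$$R(\lambda) = a \, B_c(\lambda)\, e^{-\sum_k c_k\,\varepsilon_k(\lambda)} + b + \epsilon(\lambda),$$

truncated to the physical range $[0, 100]\,\%$, with

* $B_c(\lambda)$ — the class baseline in %, a logistic rise from the
  visible into an NIR plateau. The old-root baseline sits strictly below
  the tuberous and taproot baselines at every band (emulating the markedly
  lower reflectance of aged material); the taproot baseline carries a small
  visible-range colour bump. No quantitative reflectance gap between
  classes is available from field data, so the default gap (old root at
  78 % of the tuberous baseline) is a free parameter of
  `class_profiles()`.
* $\varepsilon_k(\lambda)$ — per-analyte absorptivity, a sum of Gaussian
  peaks, two to three per analyte, placed mainly in the 720–994 nm overtone
  region with one visible peak each. Peak-centre band indices are recorded
  as ground truth for selector-recovery benchmarks.
* $c_k$ — analyte concentrations, log-normal per class, with tuberous
  medians strictly above the other classes for all three analytes
  (medians 1.60/0.45/1.30 vs. roughly a third of that elsewhere,
  `sdlog = 0.25`).
* $a \sim \mathrm{lognormal}(0, 0.08)$, $b \sim N(0, 0.8)$ — multiplicative
  and additive surface scatter, exactly the structure SNV is designed to
  remove; $\epsilon \sim N(0, 0.15)$ per band is instrument noise.

Defaults: 270 bands on 427–994 nm and an unbalanced collection of
87/30/30 samples (tuberous/taproot/old), mirroring a realistic field
collection where the accepted material dominates.

Hypercubes are built by the exact inverse of dark/white calibration,
`raw = D + (W - D) R / 100`, so `calibrate_reflectance()` recovers the
generative reflectance to numerical precision at zero noise. Background
pixels carry a constant near-dark reflectance (2.5 %) so threshold
masking is testable.

**What the generator does not emulate:** wavelength-dependent detector
noise, specular highlights, moisture/particle-size confounds, spatial
texture within a specimen, and any chromatographic reality behind the
metabolomics tables (which start at the intensity-matrix level). Passing
tests therefore demonstrate correctness of the algorithms under a
Beer–Lambert-with-scatter world, not instrument-grade robustness.

# Calibration, trimming, ROI

Reflectance calibration is the elementwise
$I = (I_0 - D)/(W - D) \times 100$; no clipping is applied, since the
formula defines none and specular pixels may legitimately exceed 100 %.
The analysis window (default 427–994 nm, inclusive) is trimmed off a wider
acquisition axis because band extremities are noise-dominated. An ROI's
spectrum is the per-band arithmetic mean over its mask. Cubes are stored
as ENVI-style text header + flat binary (BIL interleave by default); the
white reference is treated as the 100 % level — if the physical reference
tile reflects less (e.g. 80 % Teflon), reported reflectances are relative
to the tile, not absolute.

# Pre-processing

* **SNV** standardises each spectrum to zero mean and unit sample SD
  ($n-1$ denominator; the choice only affects constants).
* **Savitzky–Golay** filters use `window = 11`, `polyorder = 3` by default
  — common practice at ~270 bands; both are configurable. Derivatives are
  SG derivative filters (not finite differences) in units of per band
  index; edges are handled by the boundary-window polynomial fits, so no
  bands are lost.
* The named chains are `Raw`, `SG`, `SNV`, `1stD`, `2ndD`, `1stD-SG`,
  `2ndD-SG`; the hyphenated names apply the derivative first, then
  smoothing, per the naming order. Custom orders are available via
  explicit step lists. Where SNV is combined with other steps the package
  default applies SNV first.

# PLS core and wavelength selection

The PLS implementation is NIPALS with deflation (PLS1 for scalar
responses, PLS2 against one-hot class matrices for PLS-DA); extraction
stops early when the residual X block is numerically empty. Scores are
orthogonal by construction, and at full rank the coefficients coincide
with least squares — both properties are tested against independent
oracles.

**CARS** runs `n_runs = 50` sampling runs. Each run fits PLS (max 14
latent variables) on a random 80 % calibration subsample, ranks bands by
absolute regression coefficient, enforces the exponentially decreasing
retention fraction $r_i = a e^{-k i}$ calibrated through $r_1 = 1$ (all
bands) and $r_N = 2/p$ (two bands), then resamples retained bands with
probability proportional to normalised |coefficient|. Every run's subset
is scored by 10-fold RMSECV and the minimiser is returned. A published
description of this selector mixes a "1000 runs" Monte Carlo
cross-validation setting with "50 samplings"; the canonical CARS loop is
the 50-run form implemented here, and the run count is exposed in
`cars_config()` for anyone wanting the other reading.

**SPA** builds, from every starting band, a chain of successively
most-orthogonal bands (up to `m_max = 50`), scores each candidate subset
by the PRESS of a multiple linear regression on an SPXY calibration/test
partition (test ratio 1/3, bands standardised on the calibration set),
and returns the smallest subset whose PRESS is not significantly worse
than the minimum under an F-test at $\alpha = 0.25$
($\mathrm{PRESS}_m \le F_{1-\alpha}\,\mathrm{PRESS}_{\min}$). Exactly
collinear columns have zero orthogonal residual and can never be
co-selected.

**SPXY** is Kennard–Stone selection on the joint normalised distance
$d = d_x/\max d_x + d_y/\max d_y$; it is fully deterministic, with ties
broken by lower sample index.

**Random frog** runs a 2000-iteration subset chain from an initial
subset of size $Q = 2$. Proposals resize the subset by a normal draw
(SD = 0.3 of the current size); shrinking keeps the strongest PLS
coefficients, growing draws three times the needed bands from outside and
re-ranks the union. A better-scoring candidate (5-fold RMSECV on fixed
folds) is always accepted; a worse one with probability
$\eta \cdot \mathrm{perf}$ ratio, $\eta = 0.1$. The undamped
Metropolis-style ratio rule ($\eta = 1$, also available) was evaluated
first and rejected: the chain then wanders enough that on a minority of
seeds one genuinely informative band finishes outside the top decile of
selection probability, whereas the damped rule recovers all planted bands
at every seed tested. The final subset is the top-$k$ by selection
probability with $k$ chosen by minimal RMSECV over $k \in 2..30$
(a probability threshold mode is also provided).

Tie-breaks in all coefficient rankings go to the lower band index, making
every selector deterministic under its seed.

**Benchmarks.** Selector tests use a planted-band design: 100 samples by
270 bands with mild neighbouring-band correlation and a response carried
by 10 known bands. Exact-index coverage checks for SPA use a 60 x 60,
3-band design *without* the band correlation, because with correlated
designs an adjacent band aliases the planted one and exact-index scoring
would punish the design rather than the selector.

# Learners

* **Classifiers.** Multinomial logistic regression (`nnet::multinom`),
  RBF SVM (`e1071::svm`, cost 10 — kernel and cost are not fixed by any
  published setting, so Table-level accuracies are not exactly
  replicable even in principle), and a single-hidden-layer MLP with 50
  neurons and softmax output (`nnet::nnet`). Features are autoscaled on
  the training set.
* **LSSVM.** Solves the dual system
  $\begin{bmatrix}0 & \mathbf 1^\top\\ \mathbf 1 & K + I/\gamma\end{bmatrix}
  \begin{bmatrix}b\\ \alpha\end{bmatrix} =
  \begin{bmatrix}0\\ y\end{bmatrix}$ in one dense solve, with
  $K(u,v) = e^{-\lVert u-v\rVert^2/\sigma^2}$ and $\gamma = \sigma^2 = 2$.
  Features are centred but *not* autoscaled: SNV already sets the spectral
  scale, on which pairwise squared distances between samples are of order
  10 — commensurate with the fixed kernel width. Autoscaling 270 bands
  would inflate distances to $\approx 2p$ and collapse the kernel matrix
  to the identity (prediction of the mean); this was observed directly and
  is why the centring convention is the default.
* **ELM.** 40 sigmoid nodes, input weights uniform(−1, 1) and biases
  uniform(0, 1) under the configured seed, output weights by Moore–Penrose
  pseudoinverse (`MASS::ginv`), features autoscaled.
* **BPNN.** One hidden layer of 8 sigmoid neurons, linear output,
  full-batch gradient descent with $\eta = 0.6$ for up to 1000 epochs or
  until the target MSE $10^{-5}$ is reached. Inputs and target are min–max
  scaled to $[-1, 1]$ — the classical convention under which that learning
  rate is stable; with z-scored inputs the same rate diverges (non-finite
  loss within a few hundred epochs), which was observed directly. The
  target MSE is checked on the scaled response; the loss trajectory is
  recorded and divergence is reported with its epoch.

Every trained predictor stores its pre-processing chain, band subset, and
normalisation constants, and re-applies them at prediction time; inputs
with a mismatched band axis are refused.

# Evaluation

Classification uses a stratified 60/20/20 train/validation/test split
(largest-remainder rounding per class — an unbalanced 147-sample
collection cannot be split exactly 60/20/20 within every class, so the
allocation rule is documented rather than claimed to match any particular
published split) plus stratified k-fold cross-validation. Quantitative
models use an SPXY 2:1 calibration/prediction split.

Metrics follow the standard definitions: $R^2$ as one minus the residual
to total sum-of-squares ratio; RMSE with the $1/n$ denominator;
$\mathrm{RPD} = \sigma_y / \mathrm{RMSEP}$ with $\sigma_y$ the population
SD (n denominator) of the evaluated partition's true values, so
$\mathrm{RPD}\cdot\mathrm{RMSE} = \sigma_y$ holds identically. Perfect
predictions make RPD undefined and raise an error rather than returning
infinity. Confusion-matrix metrics are computed one-vs-rest per class and
macro-averaged (a weighted option exists); empty denominators yield 0 for
the affected class. Cohen's kappa uses
$K = (P_o - P_e)/(1 - P_e)$ and is defined as 1 in the degenerate
$P_e = 1$ case.

# Metabolomics screen

Features pass the response/occurrence filter when they reach 5000 counts
in at least 80 % of the samples of at least one root-class group (QC
samples do not count toward occurrence). "Normalisation" is per-sample
median scaling; ANOVA runs on log2 intensities (Welch optional), while
fold change is computed on raw-scale group means as the maximum pairwise
ratio — the multi-group fold-change convention is not standardised, and
this choice is deliberately the most permissive symmetric one. The screen
keeps features with $p < 0.05$ **and** $\mathrm{FC} > 2.0$, both strict,
so an exact boundary value of 2.0 is excluded. Features with zero
within- and between-group variance get $p = 1$. PLS-DA reports R²X/R²Y
(cumulative explained variance of the blocks) and Q² from 7-fold
cross-validation (folds are a free choice; 7 is a common default).
Hierarchical clustering operates on row-standardised log2 intensities
(Ward linkage, Euclidean, both configurable) and renders a blue-to-red
heatmap in dendrogram order.

# Pixel maps

`predict_pixel_map()` pushes every foreground pixel through the model's
full chain; background pixels carry `NA`. Rendering uses a red (scale
maximum) to black (scale minimum and background) gradient with per-image
bounds by default (fixed bounds are available for cross-sample
comparison). Negative predictions are rendered at the black endpoint but
left unmodified in the numeric grid. For nonlinear models the ROI mean of
pixel predictions and the prediction of the ROI-mean spectrum differ;
`map_roi_summary()` reports both without claiming equality, which holds
only for linear models. Kernel models flatten once concentrations leave
the calibrated range, so planted spatial gradients are recovered reliably
only inside the training support.

# Problem sizes and reproducibility

The bundled demonstrations and tests run on the default 147-spectrum set,
cubes up to 24 x 24 pixels, 600-feature metabolomics tables, and the
planted-band benchmarks above — sizes chosen so a complete run finishes
in well under a minute while every statistical check retains power. All
stochastic components (generators, Monte Carlo subsampling, fold
assignment, learner initialisation) are driven by explicit seeds; a run
configuration plus its seed fully determines every output, and
`run_pipeline()` writes a JSON manifest recording the seed and a content
hash of the configuration alongside its CSV reports.

# Known limitations

* The fixed literature-style hyperparameters (e.g. $\gamma = \sigma^2 = 2$,
  40 ELM nodes) are exposed but not tuned; no hyperparameter search is
  provided by design.
* The generative world is favourable to SNV/derivative pre-processing by
  construction; relative rankings of chains on real instrument data may
  differ.
* SPA's cost grows with bands x `m_max`; for axes much larger than ~500
  bands, restrict the starting-band set or pre-trim.
* The multinomial LR is effectively unregularised and will produce
  divergent weights on perfectly separable training sets; predictions
  remain well-defined.
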
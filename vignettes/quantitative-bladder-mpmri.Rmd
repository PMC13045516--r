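---
title: "Models and methods for quantitative bladder multiparametric MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for quantitative bladder multiparametric MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blademri)
```

# Scope

`blademri` quantifies bladder tumour physiology from multiparametric MRI along
two paths. The model-based path fits voxelwise signal models to
diffusion-weighted (DW) and dynamic contrast-enhanced (DCE) series and emits
parametric maps plus ROI statistics. The classification path turns 2D image
slices into fixed-length deep-feature vectors, screens them with five
feature-selection scorers, and evaluates three classifiers with ROC-based
metrics. Everything is testable offline through seeded digital phantoms with
known ground truth.

The package deliberately starts *after* segmentation and spatial
preprocessing: tumour masks are inputs on the same voxel grid as the images
(no implicit resampling — silently regridding a quantitative map corrupts it),
and N4 bias-field correction plus DICOM conversion are upstream steps for
external tools.

# Diffusion models

The DW signal at diffusion weighting $b$ (s/mm²) is modelled two ways.

**Monoexponential (ADC).** $S(b) = S_0\,e^{-b\cdot\mathrm{ADC}}$, assuming
Gaussian diffusion. Fitting is weighted log-linear least squares with weights
$\propto S^2$, the first-order variance correction after the log transform;
this recovers noiseless data essentially exactly and is fast enough for
whole-volume use. Non-positive signals (possible after noise or artefact)
force a bounded Levenberg–Marquardt fallback on the raw signal, which is
flagged.

**Non-Gaussian IVIM.** The two-compartment model with a kurtosis-corrected
tissue term,

$$S(b) = S_0\left[f\,e^{-b D^*} + (1-f)\,e^{-b D + \frac{1}{6}K(bD)^2}\right],$$

separates capillary pseudo-diffusion ($f$, $D^*$) from hindered tissue
diffusion ($D$) and its non-Gaussian deviation ($K$). The default fit is
segmented: (1) on the high-$b$ tail ($b \ge 200$ s/mm², where the perfusion
term has decayed to $e^{-200\cdot 0.02557}\approx 0.006$ of its amplitude for
a typical $D^*$) the log-signal is quadratic in $b$, giving closed-form
initial $D$, $K$ and the tissue-only intercept; (2) $f$ follows from the
measured $S(0)$ versus that intercept and $D^*$ is fitted on the full curve;
(3) one bounded joint Levenberg–Marquardt refinement of all five parameters.
Bounds are physiological — $D \in [10^{-6}, 4\times10^{-3}]$ mm²/s,
$D^* \in [4\times10^{-3}, 0.2]$ mm²/s, $f \in [0,1]$, $K \in [0,3]$ — and
also prevent the slow and fast compartments from swapping roles. Fits that
touch an interior bound, fail to converge, or land at $D^* < 2D$
(perfusion-unidentifiable) are flagged in a bit-mask diagnostics map rather
than silently reported, and ROI statistics exclude non-finite voxels and
count them.

The truncated cumulant expansion behind the kurtosis term turns upward at
$b > 3/(KD)$; the forward model clamps the tissue exponent at its minimum
beyond that point so the signal stays non-increasing and bounded by $S_0$,
and marks the evaluation. For the cohort-mean parameters the turning point
($\approx 6000$ s/mm²) is far above any acquired $b$.

A fitting protocol needs at least six distinct $b$-values spanning $b < 100$
and $b \ge 800$ s/mm²; the phantom default
$b=\{0,30,60,100,200,400,600,800,1000\}$ covers both the IVIM and kurtosis
regimes.

# DCE models

**T1 mapping.** Pre-contrast $T_{10}$ comes from a variable-flip-angle
spoiled gradient-echo (SPGR) series,
$S = M_0 \sin\alpha\,(1-E)/(1-E\cos\alpha)$ with $E = e^{-TR/T_1}$, fitted by
the standard linearisation $S/\sin\alpha$ vs $S/\tan\alpha$ (slope $E$)
followed by one bounded nonlinear refinement. Slopes outside $(0,1)$ and
angle-independent signals are non-physical and flagged, with $T_{10}$ clamped
to $[0.05, 10]$ s. The default three-angle scheme is $\{2°, 10°, 15°\}$.

**Signal to concentration.** Under the fast-exchange-limit linear relation
$R_1(t) = R_{10} + r_1 C_t(t)$, each voxel's dynamic signal is converted by
calibrating $M_0$ from the pre-contrast baseline (mean of the first
`n_baseline = 3` frames), inverting the SPGR equation for $R_1(t)$ frame by
frame, and dividing the relaxation-rate change by the relaxivity
($r_1 = 3.9$ mM⁻¹s⁻¹ by default, with $T_{10} = 1.16$ s as the default
tissue value). Saturated frames that cannot be inverted are flagged and set
non-finite instead of aborting the voxel. Negative concentrations produced by
noise are retained for fitting — clamping them would bias the kinetic
parameters — and only clamped for display. The SPGR inversion is exact for
the stated signal model, and `concentration_to_signal()` is its inverse
(round trip accurate to $10^{-9}$); a linear small-enhancement mode
($\Delta R_1 \approx \Delta S/S_{base}\cdot 1/T_{10}$) is available for
comparison but degrades as $r_1 C_t T_{10}$ grows.

**Patlak analysis.** The unidirectional two-parameter model is fitted as the
classical graphical plot: ordinary least squares of $C_t(t)/C_p(t)$ against
$\int_0^t C_p\,d\tau / C_p(t)$, slope $K^{trans}$ (min⁻¹) and intercept
$v_p$. The plasma integral is the integrand: with tissue concentration in its
place the intercept would lose its plasma-volume meaning and the plot would
not be linear for Patlak-generated data, so the package integrates $C_p$ —
this is a deliberate formulation choice, and the exactness property (the fit
returns $r^2 = 1$ and machine-precision parameters on data generated by the
model with any positive $C_p$) holds only for it. Frames before bolus
arrival, with $C_p$ below 5% of its peak, are excluded and counted.

**Extended Tofts.** The three-parameter model

$$C_t(t) = K^{trans}\!\int_0^t e^{-k_{ep}(t-\tau)}C_p(\tau)\,d\tau + v_p C_p(t),
\qquad k_{ep} = K^{trans}/v_e,$$

is evaluated on the AIF grid by trapezoidal quadrature (implemented with the
exponential semigroup recursion, so it is $O(n)$ and algebraically identical
to the full trapezoid sum) and fitted by bounded nonlinear least squares over
$(K^{trans}, v_e, v_p)$ from three starts — one Patlak-informed, two generic —
keeping the best residual. $k_{ep}$ is always derived as $K^{trans}/v_e$,
never fitted independently. Patlak's no-backflux assumption makes its
$K^{trans}$ a lower bound on the extended-Tofts value whenever $k_{ep} > 0$,
a property the test suite asserts on a seeded simulation grid.

The AIF is an explicit input (two-column table $t$, $C_p$); no haematocrit
correction is applied, i.e. the supplied curve is taken as plasma
concentration directly. The phantom module ships a bi-exponential population
shape, $C_p(t) = A_1 e^{-m_1\Delta t} + A_2 e^{-m_2\Delta t}$ after bolus
arrival, with defaults $A_1 = 5$ mM, $m_1 = 3$ min⁻¹, $A_2 = 1$ mM,
$m_2 = 0.05$ min⁻¹, arrival 0.25 min — a fast washout plus slow tail chosen
so the plasma curve is genuinely dynamic over the default 35-frame, 5
s/phase acquisition. These are configuration defaults standing in for a
measured patient AIF, not claims about any particular cohort's input
function.

# Classification path

**Feature extraction.** The extraction contract is backbone-agnostic: images
are intensity-normalised, resized to the backbone's input size, and mapped to
one fixed-length vector per image, deterministically. The built-in `stub`
backbone implements the contract as a seeded Gaussian random projection
followed by a tanh nonlinearity — deterministic, pixel-sensitive, and
dependency-free — so the whole downstream pipeline is testable without
downloading pretrained weights. Real convolutional backbones (tapping, e.g.,
a penultimate fully connected layer) plug in through the `extractor` hook of
`backbone_spec()`. Resizing uses align-corners separable linear
interpolation, which keeps an identity resize exact and never expands the
value range.

**Scorers.** Five per-feature relevance measures: one-way ANOVA F (vectorised
two-group F, with a large sentinel and flag when within-group variance is
zero but means differ), Kruskal–Wallis H (rank-based, tie-corrected,
delegated to `stats::kruskal.test`), a chi-squared statistic on per-class
feature sums (frequency-style; requires non-negative values, so the
dispatcher min-shifts signed features and the score scales linearly with the
feature), ReliefF (k = 10 nearest hits/misses by Manhattan distance on
range-normalised features, exhaustive over instances up to n = 500,
otherwise seeded sampling), and mRMR with the mutual-information difference
criterion on 10-bin equal-width discretisation. Ties always break on the
lowest feature index, so every ranking is deterministic.

**Classifiers and evaluation.** SVM (RBF kernel, unit cost, standardised
inputs), decision tree (Gini splits, seeded), and k-NN (k = 5, Euclidean on
standardised inputs) with fixed, documented hyperparameters. The default
split is a stratified 70/30 holdout with an explicit seed; feature selection
is computed on the training portion only, so held-out samples can never
influence which features are used. Test samples are scored with a continuous
decision value; AUC uses the Mann–Whitney pair-counting definition via
midranks (ties count ½), and the threshold-sweep ROC polygon's trapezoidal
area equals it identically. Ratios with empty denominators (e.g. sensitivity
with no positives) are reported as NaN with a flag, never as 0.

# Phantoms and what they do (not) show

Phantoms are pure functions of (spec, seed): block regions along the first
axis carry the ground-truth parameter sets, noiseless signals equal the
forward models to machine precision, and noise — Rician on magnitude signals
by default, Gaussian for quick tests — is applied after the truth maps are
stored. Rician noise is generated as the magnitude of a complex Gaussian
perturbation, which reproduces the expected upward bias of the mean at b = 0.

Passing the recovery suites on these phantoms demonstrates that the fitters
invert their own forward models correctly under the stated noise, with
correct bookkeeping (masking, flags, map layout). It does **not** establish
accuracy on clinical data, where partial volume, motion, imperfect spoiling,
B1 inhomogeneity, AIF measurement error and water-exchange effects violate
the forward models in ways no parameter of this package represents.

# Numerical choices and problem sizes

* Optimiser: bounded Levenberg–Marquardt (`minpack.lm`), maximum 200–300
  iterations; convergence reported per voxel, best-so-far parameters retained
  on failure.
* Quadrature: trapezoid throughout; at the default 5 s frame spacing the
  extended-Tofts forward solution matches the constant-input closed form to
  well under 0.2%, improving under grid refinement.
* Degenerate inputs fail loudly: constant images cannot be normalised,
  all-zero ROIs and single-class label vectors raise errors, flat DW decay
  pins ADC at its lower bound with a flag.
* The validation suites use deliberately small instances — 8-voxel noiseless
  map fits, 500-voxel stochastic grids, 120 replicate DCE curves, 200-sample
  feature sets — sized so the entire suite and the acceptance script each run
  in well under a minute while keeping Monte-Carlo error far inside the
  asserted tolerances.
* Stochastic bias is assessed over clean (unflagged) fits, mirroring how ROI
  statistics exclude and count failed voxels; at SNR 50 roughly 4% of
  NG-IVIM voxels hit the $D^*$ bounds and are screened by their flags.

# Known limitations

Single-label ROI fitting per call; no multi-shell diffusion-direction
handling or DKI tensor estimation; no AIF extraction from images, B1
correction, or water-exchange models beyond the fast-exchange limit; the
classification path is binary-endpoint only, with no bootstrap confidence
intervals on AUC; slice-to-patient aggregation of deep features (mean over
slices) is a documented default rather than a validated choice.
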
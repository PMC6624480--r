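---
title: "Automatic AIF estimation and perfusion mapping: models and design choices"
author: "perfaid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic AIF estimation and perfusion mapping: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Bolus-tracking (dynamic susceptibility contrast, DSC) MRI perfusion
follows a gadolinium bolus through the brain as a 4D series: a
`w x h x s` volume per frame, tens of frames a second or two apart. Every
voxel yields a tracer time-density curve (TDC), and the tissue curve is
modelled as a convolution of the arterial input function (AIF) with the
tissue's impulse response,

$$C_{tis}(t) = CBF \cdot (AIF \circledast R)(t), \qquad R(t) = e^{-t/MTT},$$

so that deconvolving each voxel's TDC against the AIF recovers the
CBF-scaled residue function, whose peak estimates CBF and whose peak
time is Tmax. Everything downstream — rCBF, Tmax, the Tmax > 6 s
ischemic region and its mismatch with the diffusion (ADC < 620) core —
inherits its quality from the AIF. The AIF is conventionally picked by
hand: a voxel in a large feeding artery whose curve has large amplitude,
small width, and fast attenuation, the morphology of a gamma-variate
bolus

$$C(t) = A\,(t - t_0)^{\alpha} e^{-(t-t_0)/\beta}, \quad t > t_0,$$

peaking at $t_0 + \alpha\beta$. This package automates that selection
two ways — a fuzzy c-means comparator and a multi-stream 3D CNN with
linear-SVM late fusion — and carries the result through deconvolution to
perfusion maps and a mismatch summary. A synthetic phantom generator
with exact ground truth supports training, testing and calibration.

## The signal model and the phantom

The phantom writes signal as $S(t) = S_0 e^{-TE \cdot C(t)}$ plus
clipped Gaussian noise, the standard DSC relaxivity form; the package's
`signal_to_concentration()` inverts it exactly as
$C = -\ln(S/S_0)/TE$, so noiseless round trips are exact and every test
against ground truth measures the method, not the conversion. The
conversion is isolated behind that one function: swapping in another
relaxivity model touches nothing else.

Default study conditions (all configurable through `phantom_config()`):

* **Geometry** 64 x 64 x 8 voxels, 40 frames at dt = 1.5 s; voxel
  0.43 x 0.43 x 5.00 mm; TE = 2.6 ms. These mirror clinical DSC
  acquisitions (512 x 512 in-plane at the same voxel size), scaled
  in-plane so a CPU trains the desk network in minutes. The full-scale
  geometry remains available via the config.
* **Bolus** gamma-variate with $A = 40$, $t_0 = 9$ s, $\alpha = 3$,
  $\beta = 1.5$ s: peak concentration about 180 a.u. at 13.5 s, FWHM
  about 6 s — a typical first-pass bolus that drops the arterial signal
  by roughly 40%.
* **Artery** a through-slice tube of radius 4 voxels (1.7 mm), i.e. a
  ~3.4 mm-diameter vessel — the calibre of the middle cerebral or
  internal carotid artery an annotator would choose. A thinner tube
  would be clinically unrealistic and, after the default 0.86 mm
  smoothing, partial-volume mixing would distort the extracted curve.
  Arterial voxels carry the bolus with ±3% amplitude jitter.
* **Tissue** per-voxel CBF uniform in [0.008, 0.012] /s (so CBV = CBF x
  MTT is a few percent, physiological), MTT uniform in [3, 5] s, bolus
  delays drawn from whole frame multiples up to 3 s. Delays are
  quantized to the frame grid deliberately: Tmax is frame-quantized by
  construction, and an on-grid delay makes the discrete residue peak
  equal CBF exactly, so deconvolution tests measure deconvolution
  rather than off-grid sampling artifacts.
* **Lesion** an in-plane disc over slices 2–7 with CBF scaled by 0.4,
  delay 7.5 s (hence Tmax > 6 s: ischemic) and MTT 6 s; a concentric
  core with ADC ~450 (below the 620 threshold; ADC is carried in
  1e-6 mm²/s so the conventional threshold applies verbatim).
  Background ADC ~800.
* **Noise** Gaussian signal noise with SD 7 a.u. against $S_0 = 1000$:
  about 10% of the typical tissue signal drop, i.e. clearly visible on
  tissue TDCs while arterial curves (25x larger) stay clean — the
  separability the AIF definition itself assumes.

The tissue curves are built with a left-Riemann discrete convolution
(`conv_matrix()`), the same quadrature the deconvolution inverts, so
noiseless recovery is exact up to SVD truncation. What the phantom does
**not** emulate: anatomy, partial-volume fractions, motion, Rician
noise, and contrast recirculation (a second small gamma lobe exists
behind a config flag, off by default). Tests passing on phantoms
therefore demonstrate algorithmic correctness and end-to-end wiring,
not clinical performance; the published clinical accuracies require
patient data this package does not ship.

## Preprocessing

`preprocess_series()` chains: a motion-correction hook (identity by
default — phantoms are motion-free, and the interface accepts any
`series -> series` function), optional slice-time correction (per-voxel
linear interpolation onto the common frame grid, ends clamped),
in-plane Gaussian smoothing (default sigma 0.86 mm = 2 voxels at the
emulated resolution; AIF estimation is famously insensitive to the
exact low-pass filter), Otsu brain masking (largest 6-connected
component plus a radius-1 closing; a deliberate simplification of
surface-based skull stripping, adequate where background is near zero),
signal-to-concentration conversion, and per-voxel linear drift removal
fitted through the baseline and tail frames.

The pre-bolus baseline length defaults to autodetection: the first
frame whose global in-mask mean drops 3 SD below the initial mean marks
bolus arrival; everything before is baseline (fallback 5 frames, always
clamped to [2, f)).

## Fuzzy c-means AIF selection

`fcm_cluster()` is textbook FCM on per-voxel min-max-normalized TDCs
(clustering by curve *shape*; amplitude would otherwise dominate the
Euclidean metric): memberships from the inverse-distance rule with
power $2/(m-1)$, centroids as membership$^m$-weighted means, stopping
when the largest membership change falls below `tol`. Defaults c = 5,
m = 2, tol = 1e-5, max 200 iterations — conventional values, all
configurable. Initial centroids are drawn from the lexicographically
sorted unique TDCs, which makes a seeded run invariant to voxel
enumeration order.

Two design points deserve justification:

* **Candidate preselection.** `select_aif_fcm()` clusters only voxels
  whose TDC peak lies in the top 5% of in-mask amplitudes
  (`candidate_quantile = 0.95`, 0 disables). Arterial voxels are well
  under 1% of the brain; clustering the whole mask at c = 5 absorbs
  them into an early-arrival tissue cluster and the selected "AIF"
  region becomes thousands of tissue voxels. Amplitude preselection is
  the standard first step in the FCM-AIF literature and restores a
  clean arterial cluster.
* **The cost function.** The arterial cluster is chosen by
  $cost = t_{peak} \times FWHM / amplitude$ on each cluster's mean
  *raw* (un-normalized) TDC — low for tall, narrow, early curves,
  encoding "large amplitude, small width, fast attenuation" in one
  scalar. The peak time is floored at one frame interval so the cost
  stays strictly positive. The function is isolated in `aif_cost()` so
  alternatives plug in.

## The multi-stream 3D CNN

The segmenter classifies, per voxel, a 4D patch `(wh, wh, s_p, f)`
centred on it, through two streams:

* the **spatial stream** reads the patch as a `(w, h, s)` volume with
  one input channel per frame (data arranged frame by frame, then slice
  by slice);
* the **temporal stream** reads it as a `(w, h, f)` volume with one
  channel per slice (slice by slice, then frame by frame), so the frame
  axis is a convolution dimension and bolus dynamics are learned as
  shapes along it.

Both streams share one topology: eight 3x3x3 convolutions (stride 1,
same padding, ReLU) with five max-pools after convolutions 1, 2, 4, 6
and 8, then two fully connected layers and a 2-class softmax. The
temporal stream's first pool uses kernel and stride 2x2x1, preserving
full temporal resolution through the early layers. Pooling is ceil-mode
so odd extents never error. The `"full"` preset carries filters
64–512 and 4096 fully connected units on 32-voxel patches; the `"desk"`
preset is architecture-isomorphic at filters 8–64, 256 units and
16-voxel patches. The desk patch is 16 rather than 32 because ceil-mode
pooling keeps 16 valid through five stages and it cuts train plus
inference compute about fourfold while exercising the identical code
path; at the emulated voxel size a 16-voxel window still spans several
vessel diameters. Training is plain mini-batch SGD with momentum on
cross-entropy (full-scale preset: batch 50, 50 epochs, lr 0.001, momentum
0.9; desk: batch 32, 8 epochs). Forward and backward passes run
through im2col + GEMM kernels (RcppArmadillo); backpropagation is
verified in the test suite against central finite differences.

Labels are grown from a manual annotation (`make_labels()`): the manual
AIF is the mean TDC of the annotated voxels, and any voxel within
Chebyshev radius `r_voxels` whose TDC correlates at least `corr_min`
(default 0.9) with it *and* peaks at least half as high is labeled
arterial. Patches pair one positive per labeled voxel with `neg_ratio`
(default 3) negatives from the brain mask — half of them near-miss
voxels within two voxels of the vessel, deliberately hard negatives —
sampled deterministically by seed. Class imbalance is handled by this
sampling ratio rather than loss weighting.

The streams' softmax scores are fused by a linear SVM (C = 1) on the
4-dimensional concatenated scores, fitted on a 20% split held out from
stream training: fitting the fusion on the streams' own training
outputs would hand it overconfident scores. At inference
(`segment_aif()`) voxels in the top 5% of TDC amplitude are scanned
exhaustively and the rest of the mask on a coarse grid (stride 4
in-plane, 2 through slice) to bound compute; the fused positives'
largest 6-connected component is the AIF region — isolated coarse-grid
false positives cannot survive this step — and its voxel-mean TDC is
the AIF.

## Deconvolution and maps

`deconvolve()` builds the lower-triangular Toeplitz matrix of the AIF
scaled by dt and inverts it by truncated SVD, zeroing singular values
below `lambda_rel` times the largest. Truncated SVD is the standard
DSC deconvolution; the delay-sensitive (non-circulant) form is used
because Tmax is read directly as the peak time of the plain response.
Default `lambda_rel = 0.2` for noisy data; 1e-6 recovers noiseless
simulations to numerical precision. rCBF is the normalized *maximum of
the deconvolved response* — the conventional CBF estimator — divided by
the in-mask median (or the mirrored-hemisphere median in
`contralateral` mode). CBV is the trapezoid ratio
$\int C_{tis} / \int AIF$ and MTT = CBV/CBF by the central volume
theorem.

One numerical caveat is documented rather than hidden: with the
left-Riemann convolution kernel the residue area embedded in the data
is the left-Riemann sum, which exceeds the continuous integral of a
decaying exponential by about dt/2, so MTT estimates carry a relative
bias near $dt/(2 \cdot MTT)$ — about 19% at dt = 1.5 s and MTT = 4 s,
under 7% at dt = 0.75 s and MTT = 6 s. The test suite exercises MTT
recovery at the finer sampling; Tmax, CBF and rCBF are unaffected.

`mismatch()` thresholds Tmax > 6 s (ischemic) and ADC < 620 (core),
multiplies voxel counts into mL, and reports the *volume difference* as
the mismatch volume (the set-difference variant is a flag) and its
ratio to the core volume — flagged infinite when no core exists but
ischemic tissue does, undefined when both are empty. An optional mask
argument restricts the computation to the brain.

## Evaluation machinery

`segmentation_scores()` gives accuracy, sensitivity, specificity,
precision and Dice ($2|A \cap B|/(|A|+|B|)$; empty-vs-empty defined as
1), with a `mip_axial` flag that collapses both masks along the slice
axis first — the comparison surface used for vessel annotations on
axial projections. Curve characteristics are amplitude, peak time
(earliest on ties) and FWHM with linearly interpolated half-max
crossings; a one-sided crossing extends to the curve boundary and sets
a `truncated` flag. Curve deltas are absolute differences. The
discrete Fréchet distance runs the standard coupling dynamic program
over points $(t_i, c_i/\text{peak of the reference curve})$ — amplitude
normalization only, matching how such curves are compared in practice;
rescaling time to [0, 1] is available as a flag (off by default) for
comparisons across different TR settings.

## Problem sizes and determinism

The shipped tests run the full pipeline at desk scale: 10 phantom cases
of 64 x 64 x 8 x 40 (8 train, 2 held out) for the CNN, 50-curve
deconvolution round trips, 100 random 16³ mask pairs against a
brute-force scorer, 200 exhaustive Fréchet enumerations, and
finite-difference gradient checks on a thin-filter network. Every
random stage — phantom synthesis, FCM initialization, patch sampling,
weight initialization, batch shuffling — consumes an explicit seed, and
equal seeds reproduce bit-identical tensors, a property the suite
asserts.

## Known limitations

Clustering and CNN accuracies reported by the tests describe synthetic
phantoms with strong arterial/tissue separability; clinical data add
partial-volume voxels, motion, susceptibility dropout and recirculation
that the generator intentionally omits. The brain masker assumes a
near-zero background (MRI magnitude air), not CT. The motion hook is an
identity. Leakage correction, block-circulant (delay-insensitive)
deconvolution and Bayesian deconvolution are out of scope.
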
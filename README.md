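# perfaid

Automatic arterial-input-function (AIF) estimation and perfusion mapping
for bolus-tracking (DSC) MRI, in R.

Quantitative stroke perfusion hinges on one curve: the AIF, the
contrast-agent concentration over time in a brain-feeding artery. Every
voxel's tissue curve is modelled as

    C_tis(t) = CBF · (AIF ⊛ R)(t),    R(t) = e^(−t/MTT),

so deconvolving tissue curves against the AIF yields the residue
function, whose peak estimates CBF and whose peak time is Tmax; the
Tmax > 6 s region (ischemic) against the ADC < 620 region (infarct
core) gives the perfusion–diffusion mismatch that guides treatment.
Manually picking the AIF voxel is slow and poorly reproducible. This
package automates it two ways and carries the result to the mismatch
report:

* **Multi-stream 3D CNN** — patches around each voxel are classified by
  two 3D convolutional streams (a spatial stream with one channel per
  frame, a temporal stream with one channel per slice; eight 3×3×3
  convolutions, five max-pools, two fully connected layers, softmax),
  combined by a linear-SVM late fusion. Training data are grown
  automatically from a manual annotation by TDC similarity.
* **Fuzzy c-means** — the classical comparator: cluster candidate TDCs,
  score each cluster's mean curve by `t_peak × FWHM / amplitude`, and
  take the lowest-cost cluster.

Around these sit NIfTI I/O, preprocessing (masking, slice timing,
smoothing, drift removal, signal→concentration), truncated-SVD
deconvolution to Tmax/rCBF/CBV/MTT maps, mismatch quantification,
evaluation metrics (confusion scores, Dice, curve characteristics,
discrete Fréchet distance), and a synthetic 4D phantom generator with
exact ground truth used throughout the tests. It is aimed at perfusion
methods researchers and at anyone needing a fully scripted, reproducible
DSC analysis chain.

## Worked example

Simulate a stroke case, select the AIF by fuzzy c-means, deconvolve,
and quantify the mismatch:

```r
library(perfaid)

ph   <- make_phantom(phantom_config(), seed = 42)
ph$series
#> <perfusion_series> 64 x 64 x 8 voxels, 40 frames | TR 1.5 s, TE 0.0026 s, voxel 0.43 x 0.43 x 5 mm

conc <- signal_to_concentration(ph$series)
conc
#> <concentration_series> 64 x 64 x 8 voxels, 40 frames | baseline 7 frames, 18272 in mask

aif  <- select_aif_fcm(conc, seed = 7)
aif
#> <aif_result> 416 ROI voxels | amplitude 181, center 13.5 s, width 6.21 s

maps   <- deconvolve(conc, aif$curve, lambda_rel = 0.2)
tmax   <- tmax_map(maps)
report <- mismatch(tmax, ph$adc_map, voxel_mm = ph$series$voxel_mm,
                   mask = ph$brain_mask)
report
#> <mismatch_report> ischemic 4.01 mL | core 0.62 mL | mismatch 3.39 mL | ratio 5.46

segmentation_scores(aif$roi, ph$vessel_truth)$dsc
#> [1] 1
```

The selected region is the simulated artery (Dice 1.0 against ground
truth); its mean curve peaks at 181 a.u. at 13.5 s with a 6.2 s FWHM —
the tall, narrow, early morphology an annotator looks for. The
mismatch report flags the simulated hypoperfused lesion (Tmax > 6 s)
minus its diffusion core, here a 3.4 mL penumbra at ratio 5.5. The CNN
route is the same shape: `train_msnet()` on annotated cases, then
`segment_aif(model, conc)`.

A thin command-line front end over these functions ships in
`inst/cli/perfaid` (subcommands `phantom`, `preprocess`, `aif-fcm`,
`train`, `segment-aif`, `maps`, `mismatch`, `evaluate`,
`curve-compare`).

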
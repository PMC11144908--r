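# nmhybrid

Hybrid radiomics + deep-feature classification of early Parkinson's
disease (PD) from neuromelanin-sensitive MRI.

## The scientific problem

Early PD is characterized by loss of neuromelanin-containing dopaminergic
neurons in the substantia nigra pars compacta (SNpc). Short-echo-time
magnitude (**setMag**) volumes — the voxelwise mean of the magnitude images
of the three shortest echo times of a multi-echo QSM acquisition — are
sensitive to neuromelanin: the SNpc appears as bilateral hyperintense
crescents whose dorsolateral "swallow-tail" signal is attenuated in PD.

`nmhybrid` is a complete, tested pipeline for classifying HC vs early-PD
cases from such volumes plus SNpc ROI masks:

- **Radiomics arm**: IBSI-style extraction of **1781 features** per case
  (107 on the original image — 18 first-order, 14 shape, 24 GLCM,
  16 GLRLM, 16 GLSZM, 14 GLDM, 5 NGTDM — plus 93 on each of 18 filtered
  images: 8 stationary-wavelet sub-bands, 5 LoG scales, square,
  square-root, logarithm, exponential, gradient). Features are filtered by
  two-rater reproducibility (**ICC(2,1) > 0.8**) and reduced by the LASSO
  (L1-penalized logistic regression, `lambda.min` by 5-fold CV).
- **Deep arm**: a modified LeNet on 40 x 40 brainstem patches
  (conv 6@5x5 → pool → conv 16@5x5 → pool → 784 → **200-unit feature
  layer** → softmax), trained with case-level 5-fold CV, best-checkpoint
  saving, and 3x geometric augmentation (scale U(0.95, 1.05), rotation
  ±5°). The network, backprop and Adam are implemented in plain R and
  gradient-checked against finite differences.
- **Fusion**: per-case deep features (slice-mean of the 4 x 200
  activations) are ranked by mean decrease in impurity over repeated
  random forests; the top 20 join the selected radiomics features
  (10 + 20 → a **1 x 30 hybrid vector**). Six classifiers (KNN, RF, LR,
  SVM, MLP, AdaBoost) are fitted on each feature set.
- **Evaluation**: patient-level **3-of-4 voting** for image-level models;
  ACC/SEN/SPE/PPV/NPV/F1; rank-based AUC with stratified bootstrap CI;
  continuous **NRI/IDI** against a baseline model; Dice for mask
  agreement.
- **Phantom generator**: every stage is exercised end-to-end on a built-in
  synthetic midbrain phantom (bright midbrain, bilateral SNpc crescents on
  4 contiguous axial slices, attenuated/shrunken swallow-tail in PD,
  exponential T2* echo decay, Rician noise, jittered second-rater masks),
  so the whole pipeline is testable without any data download.

## Worked example

```r
library(nmhybrid)

params <- phantom_params()                      # default study conditions
case   <- generate_case(params, label = "PD", seed = 42)

vol <- reconstruct_setmag(case$echoes)          # mean of 3 shortest TEs
dim(vol$intensity)                              # 64 x 64 x 12
dice(case$snpc_mask, case$rater2_mask)          # 0.904 (two-rater overlap)

vol$intensity <- normalize_intensity(vol$intensity) * 255
feats <- extract_all(resample_volume(vol),      # 0.5 x 0.5 x 1 mm grid
                     resample_mask(case$snpc_mask))
length(feats)                                   # 1781
feats[c("original_firstorder_Mean", "original_shape_VoxelVolume",
        "original_glcm_Contrast", "wavelet-HHH_ngtdm_Coarseness")]
#     original_firstorder_Mean   original_shape_VoxelVolume
#                      212.070                      456.000
#       original_glcm_Contrast wavelet-HHH_ngtdm_Coarseness
#                        0.195                        0.028

vote_patient(c(1, 1, 1, 0))                     # 3-of-4 images PD -> 1 (PD)
```

The printed numbers read as follows: the two synthetic raters agree at
Dice 0.904 (inside the 0.85–0.98 band typical of expert readers); the
case's SNpc ROI holds 456 voxels of mean setMag intensity 212 on the 0–255
scale; the texture values are the direction-averaged GLCM contrast of the
original image and the NGTDM coarseness of the HHH wavelet band; and a
patient with 3 of 4 patch-level PD calls is classified PD.

The full pipeline (simulate → preprocess → localize → extract → select →
train CNN → fuse → fit → evaluate) is one call:

```r
cfg <- pipeline_config(n_hc = 18, n_pd = 18, seed = 1)
res <- run_pipeline(cfg, variant = "hybrid")
res$report    # per-model ACC/SEN/SPE/PPV/NPV/F1/AUC (+ NRI/IDI vs radiomics)
```

A thin command-line wrapper with `simulate`, `preprocess`, `detect`,
`extract` and `run-all` subcommands is installed at `inst/cli/nmhybrid`.

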
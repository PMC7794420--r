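# prm3d

Parametric response mapping (PRM) of paired inspiration/expiration lung CT,
registration-derived functional variables, and a volumetric CNN classifier
for COPD — with a calibrated synthetic phantom cohort so the entire chain
is testable without clinical data.

## Who this is for

Quantitative-CT researchers who have registered inspiratory/expiratory
thoracic CT (NIfTI or MetaImage, Hounsfield units), a lung mask, and a
displacement field from a prior deformable registration, and who want:

* voxel-wise PRM classification into normal / functional small-airway
  disease (fSAD) / emphysema, with lung-level quantification;
* the mechanical measures derived from the registration — Jacobian
  determinant *J*, anisotropic deformation index (ADI), slab-rod index
  (SRI), and per-voxel air-volume change;
* a 3D convolutional classifier (COPD vs non-COPD) over any of those maps,
  with stratified five-fold cross-validation and full evaluation reports;
* Grad-CAM saliency volumes showing where the network looks.

## The core model

Each lung voxel carries two attenuations: HU at inspiration (total lung
capacity) and HU at expiration (functional residual capacity), after the
expiratory scan has been resampled onto the inspiratory grid. Two fixed
thresholds classify every voxel (both cuts inclusive):

| class | code | inspiration | expiration |
|---|---|---|---|
| emphysema | 64 | ≤ −950 HU | ≤ −856 HU |
| fSAD | 32 | > −950 HU | ≤ −856 HU |
| normal | 8 | otherwise | |

`Emph%` and `fSAD%` are the mask fractions of codes 64 and 32. From a
displacement field u (convention `x_insp = x_exp + u(x_exp)`) the package
computes F = I + ∇u and, per voxel, J = det F, the principal stretches
λ₁ ≥ λ₂ ≥ λ₃ of F, ADI = √(((λ₁−λ₂)/λ₂)² + ((λ₂−λ₃)/λ₃)²), SRI =
(2/π)·atan2(λ₂(λ₁−λ₂), λ₃(λ₂−λ₃)), and ΔV_air = J·β_in(x+u) − β_ex with β
the linear air fraction between −1000 HU (air) and 55 HU (tissue).

The classifier is a nine-layer 3D CNN — three blocks of 3×3×3 convolution
(32/64/128 filters), batch normalisation, ReLU and 2×2×2 max-pooling on a
32³ input, then fully connected 128/128/2 with softmax; 1,343,490
trainable parameters — trained with Adam (lr 1e-4) on cross-entropy.
See `vignette("prm3d-methods")` for assumptions, parameter meanings and
numerical choices.

## Worked example

```r
library(prm3d)

# a synthetic COPD subject: paired scans, lung mask, displacement field
params <- phantom_params()
set.seed(42)
truth <- sample_subject("COPD", params)
subj  <- generate_paired_scan(truth, params)
round(c(emph = truth$emph_pct, fsad = truth$fsad_pct, j = truth$mean_j), 2)
#>  emph  fsad     j 
#> 19.99 46.49  1.30

# PRM classification and quantification
prm <- classify_volume(subj$pair, prm_thresholds(-950, -856))
prm_summary(prm, subj$pair)
#> <qct_summary> Emph% 20.00 | fSAD% 46.51 | Normal% 33.50 | TLC 4.59 L | FRC 4.39 L

# functional variables from the displacement field
fm <- functional_maps(subj$pair, subj$field)
round(fm$scalars, 3)
#>     j   adi   sri dvair 
#> 1.297 0.153 0.632 0.221
```

The PRM-measured burdens (20.00% emphysema, 46.51% fSAD) recover what the
generator planted (19.99%, 46.49%) to within voxel quantisation, and the
voxel-median Jacobian (1.297) matches the subject's drawn target (1.297):
the full measurement chain is closed. A cohort-level demonstration,
including five-fold CNN classification and Grad-CAM export:

```r
cfg <- read_run_config()        # defaults: 40/40 subjects, PRM input
res <- run_pipeline(cfg)
res$report
```

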
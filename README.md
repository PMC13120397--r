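# specpoly

Nondestructive quantification of total polyphenol content in seeds from
near-infrared (NIR) hyperspectral images — an R implementation of the full
chemometric pipeline, for spectroscopists and ML practitioners who want a
tested, scriptable reference of each stage:

* **Imaging chain**: ENVI cube I/O, white/dark reflectance correction
  `I = (IO − B)/(W − B)`, Otsu guide-band segmentation (1290 nm) of the
  sample from the dark dish, ROI mean-spectrum extraction, replicate
  averaging, band trimming to 940–1670 nm.
* **Preprocessing**: MSC, Savitzky–Golay, first derivative, SNV — all
  fitted on calibration rows only, with stored state replayed on
  prediction rows.
* **Wavelength selection**: CARS (Monte-Carlo subsets + exponentially
  decreasing retention + |PLS coefficient|-weighted resampling, scored by
  RMSECV) and SPA (successive orthogonal projections scored by MLR
  validation RMSE).
* **Models**: NIPALS PLSR with CV-chosen components; LSSVM (RBF kernel,
  one linear solve, grid-tuned); and a multi-scale residual 1-D CNN
  (**MS-RCNN**) — parallel conv branches with kernels 13/9/5, fusion conv +
  max-pool, a two-conv residual block with identity skip, adaptive average
  pooling to 64, three fully connected layers — plus its no-skip ablation
  (**MS-CNN**) and Grad-CAM band saliency. Forward/backward passes are
  implemented in-package (BLAS matrix ops) and gradient-checked in tests.
* **Evaluation**: R², RMSE (denominator *n*) and RPD = SD/RMSE with the
  population-SD convention, under which RPD ≡ 1/√(1 − R²); a seeded 70/30
  calibration/prediction split; and a preprocessing × selection × model
  grid runner with leakage guards.
* **Synthetic data**: seeded Beer–Lambert generators (analyte Gaussians at
  1150/1210/1340/1450 nm, interferents, scatter, baseline, noise; a
  dark-scene hypercube with a bright sample disk) with recorded ground
  truth, so the whole pipeline is testable end to end.

## Worked example

```r
library(specpoly)

# 200 synthetic seed samples, 472 bands on 940-1670 nm, known truth
gen <- generate_spectra(synthetic_spectra_config(seed = 42))
sp  <- split_calibration_prediction(200, 0.7, seed = 42)
xc  <- subset_spectra(gen$spectra, sp$calibration)
xp  <- subset_spectra(gen$spectra, sp$prediction)

# CARS wavelength selection on calibration rows only
sel <- cars_select(xc, gen$y[sp$calibration], cars_config(seed = 42))
length(sel$selected_indices)
#> [1] 65


# MS-RCNN on the selected bands
net <- build_network(network_spec(), length(sel$selected_indices), seed = 1)
tr  <- train_network(net, subset_spectra(xc, bands = sel$selected_indices),
                     gen$y[sp$calibration], train_config(seed = 1))
ev  <- evaluate_model(tr, subset_spectra(xp, bands = sel$selected_indices),
                      gen$y[sp$prediction], sp$calibration, sp$prediction)
unlist(ev$metrics)
#>         r2       rmse        rpd
#> 0.94195054 0.02791145 4.15050476
```

The selected wavelengths cluster at the planted absorption features near
1150/1210/1340/1450 nm; prediction R² ≈ 0.94–0.96 across training seeds
(RPD ≳ 4, well above the RPD > 3 bar usually quoted for good quantitative
NIR prediction). A classical PLSR baseline on the full 472 bands reaches
R² ≈ 0.95 on the same split, and `run_grid()` reproduces the standard
comparison-table layout (`method, model, R2, RMSE, RPD`) over the full
preprocessing × selection × model cross product.

A command-line interface wrapping the same functions installs as
`exec/specpoly`:

```sh
specpoly simulate spectra --seed 42 --n 200 --out-x x.csv --out-y y.csv
specpoly select --method CARS --in x.csv --ref y.csv --seed 3 --out selection.json
specpoly grid --in x.csv --ref y.csv --models plsr,ms-rcnn --selection none,CARS --out results.csv
```

See the vignette (`vignettes/hyperspectral-polyphenol-pipeline.Rmd`) for
the model details, parameter choices and known limitations.

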
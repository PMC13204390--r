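# ramanreactor

Simulation and chemometric analysis of label-free Raman monitoring of
metabolic gradients in a diffusion-limited cell-culture microreactor.

A 3D-printed microreactor feeds a 15 mm culture chamber by passive
diffusion from a ~500 µL medium reservoir. Cells consume glucose and
secrete lactate and protons, so gradients of nutrients and pH develop
along the chamber; confocal Raman spectra of the extracellular medium
(600–1200 cm⁻¹) read this chemistry out label-free through the glucose
1125 cm⁻¹, lactate 853 cm⁻¹, stress-marker 680 cm⁻¹ and pH-sensitive
HEPES 1040–1050 cm⁻¹ bands. This package implements the complete
workflow as tested, reusable code:

* **Forward model** — 1-D reaction–diffusion of glucose, lactate, acid
  load (→ pH via buffer capacity) and a stress metabolite (explicit FTCS
  scheme with an enforced stability bound `D·Δt/Δx² ≤ 0.5`; Dirichlet or
  finite-reservoir boundary), plus a spectral renderer with
  Lorentzian/Gaussian bands, Henderson–Hasselbalch pH-dependent buffer
  bands, glass-window signatures, Gaussian detector noise and cosmic-ray
  spikes. The closed-form check is the semi-infinite constant-source
  profile `C(x,t) = C₀·erfc(x / 2√(Dt))`.
* **Preprocessing** — despiking (modified z-score of the second
  difference), Savitzky–Golay smoothing (window 35, order 2), asymmetric
  least squares baseline correction (`(W + λDᵀD)z = Wy`, λ = 10⁶,
  p = 0.01, 10 iterations, sparse solve), per-spectrum mean centering,
  replicate averaging.
* **Chemometrics** — PCA (truncated SVD, fixed sign convention),
  ANOVA–simultaneous component analysis (exact additive decomposition
  `X = 1m' + ΣEf + R` with per-factor PCA and sums of squares), NIPALS
  PLS1 with leave-one-out latent-variable selection, and univariate band
  calibration (`R² = 1 − SSres/SStot`).
* **Spatial analyses** — windowed band intensities (±5 cm⁻¹), parabolic
  sub-channel peak detection, gradient maps along the chamber, z-scan
  focal-plane selection by PCA clustering, and erfc diffusion-profile
  fitting with multi-start Levenberg–Marquardt.

See `vignettes/raman-microreactor-methods.Rmd` for the model, its
assumptions, and every numerical choice.

## Worked example: the four-day study

The `analysis/` directory is a numbered workflow over the package; each
script writes its tables under `results/`. Running it end to end:

```sh
Rscript analysis/01_simulate.R      # fields + 360 raw spectra
Rscript analysis/02_preprocess.R    # the §"preprocessing" chain
Rscript analysis/03_chemometrics.R  # PCA / ASCA / PLS
Rscript analysis/04_calibration.R   # band + pH calibrations
Rscript analysis/05_spatial.R       # z-scan, diffusion fit, maps
```

prints, in order:

```
Simulated 96 h on 61 grid nodes.
Day 4: glucose 17.1 mM at the reservoir face vs 4.7 mM distally; pH 6.01 -> 4.41.
Rendered 360 spectra (180 cell-condition, 180 control) on 601 channels.

Preprocessed 360 spectra: steps despike -> savgol -> als_subtract -> center
  (SG 35/2, ALS lambda 1e+06, p 0.01, 10 iters).

PCA: PC1 98.8%, PC2 0.9% of variance.
Mean PC1 in z2 by day: 237, 1109, 1752, 2277 (monotone increase).
ASCA sums of squares: day 1.04e+08 > zone 4.58e+07 (residual 2.47e+06).
Top |loading| bands of the day effect: 680, 853, 1017, 1060, 1125 cm^-1.
PLS zone discriminant separation: 4.8 pooled sd.

glucose (1125 cm^-1): R^2 = 0.9998 over 0.78125-25 mM.
lactate (853 cm^-1): R^2 = 0.9998 over 0.78125-25 mM.
pH PLS: 3 latent variables (LOO), held-out R^2 = 0.9876, RMSE 0.19 pH units.

z-scan: glass-free interval 0.6-0.9 mm; recommended focal height 0.6 mm.
Adenine 725 cm^-1 gradient: erfc fit D = 2.63 mm^2/h (simulated with 2.9).
Stress band, distal third: 41 (day 1) -> 253 (day 3) counts.
```

Reading the numbers: the finite reservoir depletes over four days, so
the whole chamber — not just the distal zone — drifts with time; that is
why the temporal factor carries the dominant ASCA variance and PC1
increases monotonically in z2, while the zone factor (spatial gradient)
is second. The day-effect loading peaks sit on the lactate (853),
stress (680) and glucose (1125) bands plus medium buffer bands. The
calibrations confirm the band intensities remain linear in
concentration through the full preprocessing chain, and the z-scan
places the focal plane in the glass-free central region of the chamber.

## Layout

```
R/                  package code (types, simulator, renderer,
                    preprocessing, chemometrics, spatial, orchestration)
analysis/           numbered workflow drivers (thin, narrative)
scripts/            acceptance.R
tests/testthat/     unit, property and end-to-end suites
vignettes/          methods vignette
results/            tables written by the analysis scripts
```
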
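---
title: "Methods: simulating and analyzing Raman-monitored metabolic gradients"
author: "ramanreactor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing Raman-monitored metabolic gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanreactor)
```

# The system being modeled

A 3D-printed microreactor holds a 15 mm culture chamber fed by passive
diffusion from a lateral medium reservoir (~500 uL). Cells seeded in the
chamber consume glucose and secrete lactate and protons; because supply
is diffusion-limited, stable gradients of nutrients, pH and oxygenation
develop along the chamber. Three zones are analyzed at increasing
distance from the reservoir: z1 (0--5 mm, well perfused), z2 (5--10 mm,
hypoxic), z3 (10--15 mm, necrotic in long cultures). Confocal Raman
spectra of the extracellular medium, acquired daily over four days at 15
replicates per zone in the 600--1200 cm^-1 fingerprint window, read out
this chemistry label-free: glucose at 1125 cm^-1, lactate at 853 cm^-1,
a purine-derivative stress marker at 680 cm^-1, and the pH-sensitive
HEPES buffer band at 1040--1050 cm^-1.

The package forward-models this experiment end to end — transport,
chemistry, spectroscopy, noise — and implements the full analysis chain
(preprocessing, PCA/ASCA/PLS chemometrics, band calibration, spatial
mapping), so that every stage is testable against known ground truth
without any instrument data.

# Reaction–diffusion forward model

`simulate_reaction_diffusion()` solves a 1-D transport/reaction system
on the chamber axis with an explicit forward-time centered-space (FTCS)
scheme. The explicit scheme was chosen deliberately over implicit
alternatives: every update is transparent, and the stability bound
`D dt / dx^2 <= 0.5` is *enforced* (violations are an error, never
silently repaired). The default grid is `dx = 0.25` mm with
`dt = 0.9 x` the stability limit; oracle comparisons against the
closed-form erfc solution use `dx = 0.1` mm, where the solver agrees to
well under 2% everywhere the concentration exceeds 5% of the source.

Reactions, restricted to where cells sit:

* glucose uptake: Michaelis–Menten, `vmax = 0.4` mM/h at unit cell
  density, `km = 0.5` mM — a typical bulk consumption scale for a dense
  (10^6 cells/mL) culture;
* lactate production at 2 mol per mol glucose (glycolytic
  stoichiometry), proton production likewise 2:1;
* pH from the accumulated, diffusing acid load via a buffer capacity of
  12 mM per pH unit (≈25 mM HEPES plus the medium's minor buffers);
* stress-marker release at 0.05 mM/h wherever glucose < 1 mM or
  pH < 6.8. This release rule is explicitly a modeling stand-in for
  unresolved biology (lysis vs secretion of purine derivatives); both
  thresholds and the rate are configurable and nothing downstream
  depends on the mechanism, only on the directional behavior (stress
  accumulates late and distally).

Diffusion coefficients default to small-molecule aqueous values
converted to mm^2/h: glucose 2.4, lactate 3.7, adenine 2.9, stress
marker 3.0, buffered acid 3.2 (0.7–1.0 x 10^-9 m^2/s).

## The reservoir boundary

Two left-boundary regimes are provided. `"dirichlet"` holds the
reservoir face at a fixed concentration — the ideal infinite reservoir,
correct for short experiments such as the 10-minute adenine diffusion
validation, and the regime in which the erfc closed form applies.
`"reservoir"`, the default for the multi-day experiment emulator, treats
the reservoir as a finite well-mixed compartment (500 uL ≈ 42 mm of
equivalent chamber length) that exchanges with the chamber and itself
depletes and acidifies. The distinction matters: with a fixed-fresh
boundary the chamber relaxes toward a spatial steady state, after which
spectra stop changing in time and spatial variance dominates
permanently. A four-day unreplaced culture is *not* in that regime — the
supply itself runs down, every zone drifts through day 4, and the
temporal factor carries the dominant variance, which is exactly the
structure the multivariate analyses are designed to resolve.

# Spectral renderer

`render_spectrum()` composes intensity as

    sum_analytes conc x (band profiles)  +  background  +  glass  +  noise

Metabolite bands are Lorentzian (FWHM 8–14 cm^-1); backgrounds are
broad Gaussians. Band positions come from the band registry (glucose
1125, lactate 853, adenine 725, stress 680, medium 980 cm^-1);
amplitudes are set so that strong bands at working concentrations reach
several hundred counts over a Gaussian detector noise of sd 10 counts —
the accumulation-averaged signal-to-noise regime of a confocal system at
moderate integration times.

**pH-sensitive bands.** A buffer is rendered as two component sets —
protonated and deprotonated — mixed by the Henderson–Hasselbalch acid
fraction at the local pH. HEPES (pKa 7.5 at 37 °C) carries the 1040
(acid) / 1048 (base) cm^-1 pair, reproducing the observed progressive
shift in position and intensity with pH. A single pKa, however,
saturates outside roughly pKa ± 1.5: spectra at pH 4 and 5 would be
essentially identical, and no linear calibration over pH 4–10 could
exceed R^2 ≈ 0.89. Real HEPES-buffered DMEM is a multi-buffer system,
so the medium model adds minor titratable components with pKa 4.2
(amino-acid carboxyl), 6.35 (bicarbonate), 7.2 (phosphate) and 9.5
(amine), each a Henderson–Hasselbalch pair of modest amplitude. Their
staggered transitions make the overall spectral response quasi-linear
across pH 4–10, which is the property that makes a linear PLS pH
calibration work on this medium at all.

**Glass windows.** The chamber is closed by two glass slides from
different manufacturers with distinct Raman signatures (bottom: 612 and
1090 cm^-1; top: 655 and 805 cm^-1; broad 40 cm^-1 Gaussians). Their
amplitude decays with distance from the window over a 0.18 mm mixing
length, so a vertical z-scan sees bottom-glass bands near z = 0,
top-glass bands near z = 1.5 mm, and clean medium in the central few
hundred micrometers.

**Cosmic rays** hit a spectrum with probability 0.1 and corrupt 1–2
adjacent channels with positive excursions far above the signal. Width
matters: at 1 cm^-1 dispersion a spike spans at most a couple of
channels, while the narrowest genuine band (8 cm^-1 FWHM) spans eight —
the despiker relies on this separation (below). Noise is additive
Gaussian (detector-dominated regime) rather than Poisson; at the
hundreds-of-counts scale the distinction is immaterial for everything
tested here.

All randomness is seeded. One global seed is expanded into per-stage
substreams by `derive_seed()` (a string hash of the stage label), so any
stage can be rerun in isolation and identical seeds give bit-identical
spectrum sets.

# Preprocessing chain

`preprocess_pipeline()` applies, per spectrum: despiking →
Savitzky–Golay smoothing → ALS baseline subtraction → mean centering →
(optionally) replicate averaging, and logs every parameter used.

**Despiking.** Channels whose modified z-score of the second difference
exceeds 8 are cosmic-ray candidates; flagged runs wider than 4 channels
are vetoed as genuine spectral features (a 1–2-channel spike contaminates
at most 4 second-difference positions, while a band's curvature run is
wider). Candidates are repaired by linear interpolation across the
flanking clean channels. The veto is what keeps sharp bands intact even
on noise-free synthetic spectra, where the z-score has no noise floor to
calibrate against.

**Smoothing.** Savitzky–Golay, window 35, order 2 — wide enough to
suppress channel noise, and order-2 so that locally quadratic peak tops
pass through unchanged. Boundaries are handled by off-center polynomial
evaluation within the first/last full window; no padding, so no
artificial edge peaks near 600 cm^-1.

**ALS baseline.** Eilers-style asymmetric least squares: iterate
`(W + lambda D'D) z = W y` with `w_i = p` where `y_i > z_i`, else
`1 - p`, for 10 iterations, solved with sparse banded matrices (cost
linear in channels). Defaults: `lambda = 1e6`, `p = 0.01`. The
smoothness penalty deserves comment because it is the single most
consequential parameter in the chain. Its working range in chemometrics
practice is 1e5–1e8; at `lambda = 1e6` the baseline bends over ~32
channels (`lambda^(1/4)`) and slides under the peaks. If lambda is made
very small (e.g. 1e-6), the penalty is negligible against even the
smallest asymmetry weight and the "baseline" simply reproduces the
signal: the corrected spectrum collapses to amplified fourth-difference
noise, peak positions become unrecoverable and band/concentration
linearity is destroyed (we measure R^2 ≈ 0.7 against a known series, vs
> 0.999 at 1e6). Both regimes are reachable through the configuration;
the default is the one under which the method's published outputs —
resolvable band trends and near-perfect calibrations — are possible.

Two properties of converged ALS are worth knowing. First, the estimate
sits a small equilibrium offset *above* the true baseline near peaks
(scale: `p x` peak area spread over a relaxation length), so recovery
accuracy is best quoted on channels away from bands and is naturally
relative to the baseline level; at the renderer's fluorescence scales
recovery is within 2%. Second, "baseline below the signal" holds for
the noise with margin but not pointwise: on noisy peak-dominated input
about 85% of channels lie above the p = 0.01 baseline (versus ~50% for
a symmetric fit), not the idealized `1 - 2p`.

**Centering.** The corrected spectrum is centered by its mean intensity
(output mean exactly 0). No variance scaling is applied — the intensity
scale carries the calibration information the band analyses use.

**Averaging** (by any metadata keys, e.g. zone × day) is available as
the final step but off by default: the multivariate analyses run at
replicate level.

# Chemometrics

**PCA** (`spectra_pca()`): column-mean centering, truncated SVD, scores
`U S`, loadings `V'`. Sign convention: the largest-magnitude element of
each loading is positive, making score trajectories reproducible. An
uncentered variant serves the ASCA effect matrices, which are centered
by construction. Degenerate input (identical spectra) is rejected rather
than returning arbitrary components.

**ASCA** (`asca()`): the designed data matrix is split into grand mean,
one effect matrix per factor (each row the deviation of its
factor-level mean spectrum from the grand mean) and a residual;
additivity is exact by construction and verified to 1e-10 in tests. PCA
of each effect matrix yields the per-factor score trajectories and
loading spectra; factor sums of squares quantify which design factor
dominates. Interaction terms are off by default (factors are analyzed
separately, matching how the experiment is interpreted); a two-factor
interaction flag exists. For unbalanced designs the level means are
computed regardless, but the zero-column-mean property of effect
matrices is only guaranteed balanced.

**PLS** (`pls_fit()`): single-response NIPALS exactly as classically
stated (weights from `X'y`, scores, x/y-loadings, deflation), with
coefficients `B = W (P'W)^{-1} q`. At full rank this reproduces the
minimum-norm least-squares solution (tested against an SVD oracle); the
scores are mutually orthogonal. The latent-variable count for pH
calibration is chosen by leave-one-out RMSE, capped at 5. Zone analysis
uses coded responses (±1 for a two-zone contrast); because day-to-day
drift dominates the raw latent scores — as it does in the real
experiment's latent projection — zone separation is quantified along
the fitted discriminant axis (the predicted score), not in raw LV1/LV2
coordinates.

**Band calibration** (`linear_calibration()`): ordinary least squares of
windowed band intensity against concentration with
`R^2 = 1 - SS_res/SS_tot`.

# Spatial analyses

Band values are windowed means (±5 cm^-1 by default) rather than
single-channel heights — robust to sub-channel drift, and it makes the
1040-vs-1041 and 680-vs-685 cm^-1 center ambiguities (different
analyses quote either) immaterial; the registry stores one canonical
center per band. `detect_peak()` refines the argmax by parabolic
interpolation through three channels and reports a boundary with a
flat-peak warning on monotone windows.

`zscan_select_focus()` runs PCA on the z-scan, takes the score centroid
of the middle third of focal heights, and accepts the maximal contiguous
run of spectra within `median + 5 MAD` of the middle-third distance
distribution. The 5-MAD width is a robustness choice: with only ~5
middle-third points a 1-MAD ball would reject legitimately clean spectra
by sampling noise, while glass-contaminated spectra sit one to two
orders of magnitude further out, so any factor between ~3 and ~20 gives
the same answer. The recommended focal height is the clustered point
closest to the cell layer at or above a 0.3 mm clearance; if the anchor
spectrum itself fails the distance test the function reports failure
rather than guessing.

`fit_diffusion_profile()` fits `I(x) = C0 erfc(x / (2 sqrt(D t)))` by
Levenberg–Marquardt with multi-start over log-spaced D in [1e-3, 10]
mm^2/h (covering small-molecule aqueous diffusion at this scale);
constant profiles are rejected as unidentifiable.

# Problem sizes

The workflow runs at desk scale by design: the default study is 3 zones
× 4 days × 15 replicates (180 spectra, plus a matched cell-free control
device), the pH calibration uses 30 training and 10 held-out spectra
across pH 4–10, calibrations use 6-point two-fold dilution series with
3 replicates per level, and the z-scan is 16 spectra. The full analysis
chain over all of these completes in well under a minute of compute per
script on a single CPU.

# What passing tests do and do not show

The generator emulates the acquisition design, transport physics,
band-level chemistry and detector statistics of the experiment. It does
*not* emulate: lateral (2-D/3-D) transport or the reservoir's geometry
beyond a volume; oxygen as an explicit species (its effects are folded
into the stress rule); cell growth, death and detachment; fluorescence
photobleaching dynamics; wavenumber miscalibration or drift between
sessions; Poisson photon statistics; or biological replicate-to-replicate
variability beyond detector noise. Tests passing on these synthetics
therefore certify that the *analysis chain* is correct — that it
recovers what was put in, at the stated noise — not that the biological
conclusions of any particular experiment are valid. The directional
checks (glucose falls, lactate rises, stress accumulates distally and
late, time dominates zone in the ASCA variance split) verify that the
pipeline preserves the structure the forward model injects, under the
same design, noise and preprocessing as the full workflow.

# Known limitations

* The stress-release rule is phenomenological; only its directional
  consequences are asserted anywhere.
* The pH–spectrum map is monotone and PLS-recoverable by construction;
  absolute band positions of the buffer components are plausible, not
  instrument-matched.
* The finite-reservoir boundary treats the reservoir as well mixed;
  a real reservoir stratifies.
* The erfc profile fit assumes a semi-infinite medium and a constant
  source; it is applied only to early-time data where both hold.
* ASCA significance is not tested (no permutation machinery) — effect
  sums of squares are reported descriptively.
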
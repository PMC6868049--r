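---
title: "Radio-frequency radiomics on a synthetic ultrasound cohort: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radio-frequency radiomics on a synthetic ultrasound cohort: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scientific question

Clinical B-mode ultrasound is a display product: the radio-frequency (RF)
echo signal is envelope-detected, gain-compensated, log-compressed,
decimated and smoothed before a radiologist ever sees it. Those steps are
machine- and operator-dependent, and they destroy quantitative information —
frequency-dependent attenuation, envelope statistics, and local spectral
heterogeneity — that is tied to tissue microstructure. This package asks a
methodological question: **if two lesion classes differ in those RF-domain
tissue properties, does a radiomics pipeline built on parametric maps of the
original RF signal classify them better than the same pipeline built on the
display grayscale image?**

Because clinical RF data are rarely shared, the package includes a synthetic
RF cohort generator with known ground truth, so every stage of the pipeline
can be validated against the parameters that generated the data.

## The RF signal model

Each frame is a rectangular scan-line grid: `n_scanlines` lateral lines of
`samples_per_line` axial samples, sampled at `fs` (default 20 MHz) with a
pulse centered at `fc` (default 3 MHz), axial step `c / (2 fs)` (speed of
sound 1540 m/s, pulse-echo round trip). A scan line is modeled as

1. **Scatterer reflectivity**: complex white Gaussian noise, optionally
   Bernoulli-thinned at low `scatterer_density` to model sparse scatterers.
2. **Pulse convolution**: blockwise convolution with a Gaussian-modulated
   analytic pulse. The fractional bandwidth (default 0.6) is the FWHM of the
   amplitude spectrum divided by `fc`.
3. **Envelope statistics**: the per-sample field after convolution is
   complex Gaussian with known variance, so the envelope is Rayleigh. A
   probability-integral transform maps it exactly onto a Nakagami(`m`,
   `omega`) law: `U = pgamma(|g|^2, 1, rate = 1/sigma^2)` followed by
   `E = sqrt(qgamma(U, m, rate = m/omega))`. The RF sample is
   `E * cos(arg g)`, keeping the phase (and hence the spectrum) of the
   convolved field. The envelope distribution is therefore *exact*, not
   asymptotic — the generator's Nakagami parameters are recoverable to
   estimator precision.
4. **Spectral heterogeneity**: within each depth block (256 samples) of each
   line, the pulse center frequency is perturbed by a factor
   `1 + N(0, spectral_jitter_sd)`. This produces line-to-line and
   depth-to-depth variation of the local spectrum without changing the
   envelope statistics appreciably.
5. **Attenuation**: a cumulative one-way amplitude factor
   `10^(-fc_MHz * cumsum(alpha * dz_cm) / 20)`, so the local slope of the
   log power versus depth equals `-alpha * fc` dB/cm with `alpha` in
   dB cm^-1 MHz^-1.

A lesion is an ellipse in the scan-line grid with its own tissue class; its
bounding box (dilated slightly) is the analysis ROI, and four boundary
markers are carried so the ROI can also be re-derived from a marker-based
polygon (`roi_from_markers()`), emulating manual segmentation.

### What the generator does and does not emulate

It *does* give physically meaningful attenuation, exact envelope statistics,
realistic speckle correlation (pulse-limited resolution cells), depth-
dependent SNR, and a display pipeline (TGC, log compression, decimation,
smoothing). It does *not* model diffraction/beamforming (no aperture, no
focusing), sector geometry, phase aberration, reverberation or shadowing
artifacts, or spatially varying backscatter inside a class. Those effects
mainly add nuisance variance; the package's purpose is a controlled test of
the processing chain, not a transducer simulation.

## The two lesion classes

The cohort contains two classes (labelled positive and negative, 21 + 21
lesions by default) that differ in three tissue properties:

| parameter | positive | negative | map that senses it |
|---|---|---|---|
| attenuation `alpha` (dB cm^-1 MHz^-1) | 0.8 | 0.5 | DEA |
| Nakagami `m` | 1.0 | 1.0 | (envelope shape, held equal) |
| Nakagami `omega` | 1.0 | 1.0 | OND |
| scatterer density | 12 | 12 | — |
| spectral jitter SD | 0.07 | 0.04 | SDSD |

Per-lesion biological variability is added by jittering each parameter
around its class value (5% SD for attenuation and the Nakagami parameters,
0.01 for spectral jitter) and by varying lesion size and position.

These defaults are a deliberate design choice, fixed once during
development: the class contrast lives in *quantitative* RF-domain properties
(attenuation slope and spectral heterogeneity) while first-order envelope
statistics are held equal. If instead the classes differ strongly in the
Nakagami shape `m`, the speckle *texture* itself separates them and even the
grayscale control classifies nearly perfectly — a legitimate physics
outcome, but one that makes the comparison between grayscale and RF-domain
models uninformative. The frozen defaults keep all three parametric maps
informative (one-way ANOVA on the per-lesion map means separates the groups
on all three) while leaving the grayscale image only weakly informative, so
the pipeline comparison measures what it is meant to measure.

## From RF to images

Four 8-bit ROI images feed the texture battery:

* **GM (grayscale control)** emulates the clinical display: Hilbert
  envelope, adaptive time-gain compensation (`tgc_compensate()`, mean depth
  profile smoothed over 129 samples), 60 dB log compression, axial
  decimation by 4 to a display-like grid, 3×3 smoothing
  (`display_bmode()`), then per-ROI z-normalization clipped at ±3 SD
  (`znormalize_image()`). The normalization reflects clinical reality —
  absolute display brightness is operator- and machine-dependent, so only
  relative texture should carry information.
* **DEA** — local attenuation: least-squares slope of the windowed log power
  versus depth (8 axial sub-windows per window), in dB/cm.
* **OND** — Nakagami scale: `omega_hat = mean(R^2)` per window; the shape
  estimate `m_hat = mean(R^2)^2 / var(R^2)` is kept as a diagnostic layer.
* **SDSD** — spectral heterogeneity: the SD, over the pulse's −20 dB band,
  of the window's dB spectrum minus the mean dB spectrum of the shallowest
  window row (a depth-reference that removes the pulse shape and leaves
  local deviation).

Maps use 128 × 8-sample windows stepped 64 × 4 (axial × lateral). Windows
that cannot be computed (degenerate content) are mean-imputed and counted.
Maps are rendered to 8 bits on *fixed physical ranges* (DEA −8…2 dB/cm, OND
0…1, SDSD 0…8 dB) — the digital analogue of a fixed colormap — so the map
*level*, not only its texture, can carry class information across lesions.
The standalone `render_map()` keeps a per-map min–max default.

## Feature battery: 70 × 5 bands × maps

For each image, 70 features are computed: 16 histogram features, 23 GLCM
(distance 1, four directions, symmetric, averaged), 13 GLRLM, 13 GLSZM
(8-connected zones) and 5 NGTDM features, on a 32-level quantization of the
8-bit range. The same 70 are computed on the four sub-bands of a one-level
Haar transform (LL/LH/HL/HH, odd dimensions edge-replicated, sub-band masks
by 2×2 majority), giving 350 features per image. Model layouts:

* **GM** — grayscale only (350)
* **DM** — DEA map (350)
* **DOM** — DEA + OND (700)
* **DOSM** — DEA + OND + SDSD (1050)

`feature_manifest()` freezes the naming and ordering
(`<map>__<band>__<family>__<feature>`).

## Feature selection: iterative sparse representation

Features are ranked by the mean absolute coefficient of an L1-penalized
least-squares representation of the ±1 label vector, fit on 100 stratified
80% subsamples (features standardized within each subsample). Survivors
exceed the threshold `tal = 0.004`. The penalty defaults to `"auto"`: a
small stability grid (fractions of the null penalty `lambda_max`) scored by
the top-20 Jaccard stability across probe subsamples. The solver is
`glmnet` with a tight convergence threshold (1e-13); the test suite checks
it against an independent coordinate-descent implementation.

## Classification and evaluation

An RBF-kernel SVM (cost 1, gamma `1 / (p · mean variance)`) is trained on
per-fold standardized features under leave-one-out cross-validation. The
top-k sweep evaluates nested feature sets k = 1…k_max and picks the best k
by accuracy, ties broken by AUC then smallest k. Reported curves: ROC with
trapezoidal AUC (verified against the Mann-Whitney statistic) and DeLong
confidence interval, precision-recall, and decision curves from
Platt-calibrated probabilities.

Two evaluation modes exist. The default `"pooled"` mode performs selection on
the full sample and cross-validates only the classifier — a protocol common
in the radiomics literature whose selection step leaks label information, so
its AUCs are optimistic. The `"nested"` mode re-runs selection inside every
LOOCV training fold and is the honest estimate. Both are exposed because the
package's point is to reproduce and examine the pipeline, not only its best
version.

## Problem sizes and runtime

Defaults: 42 lesions of 128 × 2048 samples (~25 s to simulate a cohort on
one core), 1050 DOSM features per lesion, 100 selection iterations, LOOCV
over 42 folds. A full four-model run at `k_max = 15` takes well under a
minute after simulation.

## Limitations

* The generator's realism gaps listed above (no beamforming, no artifacts).
* With 21 + 21 lesions, AUC estimates carry wide confidence intervals, and
  LOOCV with per-fold standardization is known to be pessimistically biased
  at chance level.
* The `"pooled"` evaluation mode is optimistic by construction; use
  `"nested"` for honest error estimates.
* The class contrast is a design parameter, not an empirical claim about any
  disease; conclusions transfer only as statements about the processing
  chain.
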
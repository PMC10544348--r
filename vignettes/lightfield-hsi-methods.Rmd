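---
title: "Models and methods behind lightfieldHSI"
author: "lightfieldHSI authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lightfieldHSI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lightfieldHSI)
```

# The imaging chain being modelled

Snapshot lightfield hyperspectral cameras pair a large monochrome sensor
with a microarray of lenslets, each carrying its own narrow band-pass
filter. A single exposure therefore yields, per lenslet, one sub-image of
the scene taken through one spectral band and from one slightly displaced
viewpoint. The device class modelled here has 66 lenslets whose filter
centre wavelengths span 350--1000 nm with a full width at half maximum
(FWHM) of 10 nm, and its vendor pipeline reconstructs a hypercube of 155
fixed spectral bands from those 66 measurements. In the intra-operative
setting this enables diffuse-reflectance spectroscopy of exposed tissue at
video-compatible rates: tissue types differ in their optical properties,
so their reflectance spectra differ even where RGB appearance does not.

`lightfieldHSI` implements that chain desk-scale and end to end:

1. **phantom scenes** with exact ground truth (`makeTilePalette()`,
   `renderCheckerScene()`, `renderTissueScene()`);
2. a **forward camera model** (`simulateCapture()`): illuminant, filter
   bank, per-lenslet parallax, 12-bit sensor with shot and read noise,
   plus white and dark reference stacks;
3. **reconstruction** (`reconstruct()`): reference correction,
   parallax registration and regularised spectral inversion;
4. **colorimetry** (`spectrumToXYZ()`, `xyzToSRGB()`, `xyzToLab()`,
   `ciede2000()`, `srgbRender()`);
5. **ROI spectroscopy** (`extractRoiSpectra()`, `l1Normalize()`,
   `rejectSaturated()`, `validateAgainstReference()`).

Because no raw clinical acquisitions are publicly deposited for this
device class, every quantitative claim the package makes is evaluated on
its own synthetic scenes, where ground truth is known exactly.

# Forward model

For lenslet $i$ with transmission $F_i(\lambda)$ (Gaussian, peak 1,
$\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$), illuminant spectral power
$L(\lambda)$ and per-pixel reflectance $r(x,\lambda)$, the expected band
radiance is

$$ m_i(x) = \sum_\lambda L(\lambda)\, F_i(\lambda)\, r(x_i, \lambda)\,
\Delta\lambda, $$

where $x_i$ is $x$ displaced by the lenslet's parallax
$\delta_i = K\, b_i / Z$ ($b_i$ baseline in mm, $Z$ depth in cm, $K$ the
disparity scale in px·cm/mm). Digital numbers are
$\mathrm{DN} = \mathrm{clip}(\mathrm{round}(g\, m_i + \varepsilon), 0,
4095)$ with Poisson shot noise taken on the expected DN and Gaussian read
noise $\varepsilon$.

Key parameter choices, all configurable:

* **Filter bank** — 66 Gaussian filters, centres evenly spaced over
  350--1000 nm (10 nm pitch), FWHM 10 nm. The commercial filter responses
  are proprietary; equal spacing and Gaussian shape are explicit modelling
  assumptions, and `FilterBank` validity re-measures every FWHM by
  half-maximum crossings (tolerance 2%).
* **Lenslet layout** — a 6×11 centred lattice with 1 mm pitch (the true
  arrangement is unpublished). The disparity scale defaults to the value
  giving a 3 px maximum disparity at 25 cm depth, and the disparity
  actually applied is always recorded in the `CaptureSet` so registration
  can invert it exactly.
* **Sensor** — 12 bit (full scale 4095 DN), read noise 2 DN, shot noise
  on. `exposureGain = NA` auto-exposes the brightest white-reference
  lenslet to 80% of full scale, which keeps bright tiles safely below
  saturation while preserving SNR.
* **Illuminant** — `xenonSPD()`: a broad smooth hump plus narrow additive
  emission peaks hard-windowed to 750--900 nm, emulating the
  characteristic NIR ripple of xenon sources. The ripple is windowed
  exactly so the "peaks confined to 750--900 nm" contract is testable
  without tail tolerances.
* **White reference** — a uniform reflector of reflectance 0.95 (a
  typical calibrated tile) imaged at the same depth.

# Reconstruction

**Reference correction.** Per pixel and lenslet,
$R = (S - D)/\max(W - D, \epsilon)$ with $\epsilon = 1$ DN guarding dead
reference pixels (flagged invalid rather than silently patched). Because
the white tile reflects 0.95 rather than 1, `reconstruct()` multiplies the
corrected stack by the recorded white-tile reflectance so hypercubes are
absolute reflectance; without this every spectrum would carry a +5.3%
bias.

**Registration.** With recorded geometry each lenslet is shifted by
$-\delta_i$ with bilinear subpixel resampling (`registerKnown()`). Without
it, `registerEstimate()` searches integer shifts within ±`maxShift` px
maximising zero-mean normalised cross-correlation against the central
lenslet, ties broken toward zero; texture-free images fall back to zero
shift with a warning. Both paths assume a planar scene (one global shift
per lenslet); per-block disparity for non-planar scenes is a known
limitation of this design and out of scope here.

**Spectral inversion.** Recovering 155 bands from 66 measurements is
underdetermined; the vendor algorithm is undisclosed. The package solves,
per pixel,

$$ \min_r \lVert A r - m \rVert^2 + \lambda_{\mathrm{reg}}
\lVert \Delta^2 r \rVert^2, $$

with $A_{ik} = F_i(\lambda_k)\Delta\lambda$ row-normalised so a flat unit
reflectance maps to measurement 1, and $\Delta^2$ the second-difference
operator. This is a deliberate, documented reimplementation choice — a
Tikhonov-smoothed least squares — not a reproduction of the vendor
pipeline. Defaults: $\lambda_{\mathrm{reg}} = 10^{-3}$, second-order
smoothness, non-negativity by clipping (off by default). At
$\lambda_{\mathrm{reg}} = 0$ the normal equations are singular and the
solver refuses with an instructive error rather than returning noise.
Reconstructed reflectance is clipped to $[0, 1.5]$ — super-unity values
stay visible for specular diagnostics — and clip events are counted in
the cube's provenance.

Numerical details worth knowing:

* Filter transmissions below $10^{-10}$ (beyond ~7σ) are truncated to
  exact zero in $A$, which makes the "every output band has filter
  support" check meaningful.
* The system matrix omits the illuminant: white referencing cancels
  $L(\lambda)$ within each narrow band, so the residual model mismatch is
  second order in the band width. The illuminant-invariance test bounds
  it at < 0.02 reflectance.
* Population (not sample) standard deviation is used for ROI spread, as
  the per-structure pixel sets are complete populations of the annotation.

# Colorimetry convention

The hypercube is white balanced, i.e. the illuminant is already divided
out, so spectra are integrated against the 2° observer under equal energy,
normalised so a perfect reflector gives $Y = 1$. A fixed Bradford
chromatic adaptation then maps the observer's own equal-energy white to
D65 (sRGB's native white) inside `spectrumToXYZ()`. This makes the three
conventions cohere exactly: a flat unit spectrum maps to the D65 white
point, renders as display white, and every flat gray sits on the neutral
axis ($a^* = b^* = 0$) of the D65-referenced CIELAB used by
`xyzToLab()`. `xyzToSRGB()` itself is the plain IEC 61966-2-1 matrix and
gamma with clip-and-flag gamut handling.

The colour-matching functions ship as a 5 nm table over 360--830 nm
generated from a published multi-lobe Gaussian analytic fit to the CIE
1931 observer (no network fetch, no redistribution question). All colour
comparisons in the package are internal — measured and reference spectra
pass through the same functions — so fidelity verdicts do not depend on
the residual error of that fit.

CIEDE2000 is implemented in full (G factor, $S_L, S_C, S_H$, $R_T$) and
tested against an independently coded scalar oracle on randomised Lab
pairs. One caveat found during testing: exactly antipodal hues
($|\Delta h'| = 180°$) sit on a genuine discontinuity of the mean-hue
rule, where floating-point noise selects the branch; the formula itself is
discontinuous there, so agreement is only asserted away from that set.

# What the synthetic scenes do and do not emulate

The checker scenes reproduce the *validation geometry* of a physical
colour-checker acquisition: constant-spectrum tiles, known reference
spectra, tile-centre sampling (default 50% of the tile side, a
configurable stand-in for the unspecified "central square" window).
Chromatic tiles are smooth 1--3-bump Gaussian mixtures in [0.02, 0.95];
neutral tiles are exact flat grays. The tissue scenes reproduce the
*analysis workflow* — labelled structures, mean ± sd spectra, L1
normalisation, blood-tint red-shift — with illustrative smooth spectra,
not measured tissue optics; the blood-like curve is a fixed logistic
(low below 600 nm, high above 620 nm) committed as a package fixture.

Passing tests therefore demonstrate that the *pipeline* is correct and
self-consistent under its stated assumptions (planar scene, Gaussian
bank, smooth spectra). They do not certify performance on real tissue:
real spectra are not band-limited the way these phantoms are, real
parallax is depth-varying, and real filter responses are not exactly
Gaussian.

# Problem sizes and reproducibility

The default fidelity experiment (`runCheckerExperiment()`) uses a 96×144
px, 24-tile checker with 155 scene bands and 66 lenslets — large enough
that every tile keeps >100 centre pixels after shrinking, small enough to
run in a couple of seconds. Unit tests use 8--16 px tiles. Every
stochastic operation takes an explicit seed and restores the caller's RNG
state, so identical (parameters, seed) pairs are bit-reproducible; the
checker's palette seed is fixed (7) while the sensor seed varies, so
noise-robustness runs probe the same target.

Measured on these sizes: noiseless max per-tile CIEDE2000 ≈ 0.03,
noisy (shot + 2 DN read) ≈ 0.28 — comfortably inside the < 2
"imperceptible" and < 6 "acceptable" bands used to judge colour fidelity.
These numbers are recomputed, not quoted, by `scripts/acceptance.R` and
the test suite.

# Known limitations

* Planar-scene registration only; no per-block disparity estimation.
* No per-lenslet vignetting or flat-field model beyond white referencing.
* The Gaussian equal-spaced bank is an assumption; invertibility claims
  hold for this bank, not for the proprietary one.
* Radiative-transfer tissue modelling is out of scope; tissue phantoms
  mix spectra convexly and nothing more.
* Mosaic-pattern snapshot sensors are a different acquisition class and
  are not modelled.
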
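---
title: "Single-cell multimodal radiography: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell multimodal radiography: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radiocell)
```

`radiocell` measures three quantities on the same field of view of
radiolabelled cells grown on a scintillator crystal: per-cell **dry mass**
from quantitative phase microscopy (QPM), **cell-cycle phase** from
two-channel FUCCI fluorescence, and decay-corrected **[18F]FDG counts per
minute** from radioluminescence microscopy (RLM). Because no raw data of
this kind are publicly deposited, the package ships a first-class,
seeded synthetic-data generator that emulates the whole acquisition; every
processing stage is validated by parameter recovery against the generator's
ground truth.

## The measurement models

### Dry mass from phase

An off-axis interferometer superposes a tilted reference beam on the sample
beam, producing straight carrier fringes that are locally distorted by the
cell-induced optical path difference. We model the recorded intensity as

$$I(x, y) = A + B \cos\!\big(2\pi \mathbf{f}_c \cdot \mathbf{x} + \Phi(x, y)\big),$$

with carrier frequency $\mathbf{f}_c$ and phase map $\Phi$ in radians.
Demodulation selects the carrier sideband in the 2-D spectrum with a
circular window of radius equal to half the carrier magnitude (the
classical trade-off between resolution and zero-order leakage), tapered
over its outer 30% with a raised cosine to limit ringing; the window is
shifted to baseband and inverse transformed for both the sample and the
empty-field background frame, and the per-pixel phase is the argument of
the sample field times the conjugate background field. Any residual
sub-pixel carrier mismatch cancels exactly in that product.

The wrapped phase is unwrapped by a least-squares (Poisson) solve of the
wrapped gradient field with Neumann boundaries, via a mirrored FFT. For
compact smooth cells the gradient field is residue-free and the solve is
exact to machine precision. A second-order polynomial surface fitted on
cell-free pixels (selected robustly by two rounds of residual trimming) is
subtracted so the background is centred at zero — without it, residual
tilt biases the mass integral.

Dry mass follows from the phase integral

$$m = \frac{\lambda}{2\pi\alpha} \iint \Phi(x, y)\, dx\, dy,$$

with $\lambda = 0.633\ \mu m$ (He-Ne) and the specific refraction increment
$\alpha = 0.18\ \text{mL/g} \equiv 0.18\ \mu m^3/\text{pg}$; with all
lengths in micrometres the integral (a plain Riemann sum over the mask
pixels times the pixel area) yields picograms directly. The integral is
evaluated over the *undilated* segmentation mask.

### Cell cycle from FUCCI fluorescence

Each channel is divided by its own empty-field background image (smoothed;
must stay strictly positive) to cancel the nonuniform excitation field,
the mean of an empty region is subtracted, and pixels below a noise
threshold (3 empty-region standard deviations by default; the reference
protocol states thresholding but no value) are zeroed. Channel intensities
are then summed over each cell mask and the FUCCI logic applies: red only
→ G1, green only → S/G2/M, both → G1/S, neither → M/G1. "Expressing"
means the sum exceeds a threshold that defaults to the summed-noise scale
(3 × empty-region pixel SD × √area). The four rules are exhaustive and
mutually exclusive, and manual overrides are an explicit, recorded input —
never silent. M/G1 is retained in the state space although the reference
data set contained none.

### Counts from radioluminescence

RLM frames (recorded at 8 × 8 binning, 5 µm per binned pixel) are
dark-corrected by subtracting the temporal mean of a dark stack. Per
frame, events are found by binarising at the detector threshold (700 ADU),
suppressing shallow maxima with an h-maxima step (height 100 ADU), and
labelling connected components. Each component yields an event with an
intensity-weighted centre of gravity, a maximum-Feret length in binned
pixels, and a spectral sharpness score. Classification:

* **long** — length above 10 binned pixels (50 µm): shallow-angle
  positrons, rejected;
* **diffuse** — high-frequency spectral energy fraction below the
  sharpness cutoff: gamma interactions deep in the crystal, rejected;
* **sensor hit** — single-pixel saturated impulse, rejected;
* **short** — everything else: near-perpendicular positrons, counted at
  their centroid.

Two detector parameters are textual reconstructions of an externally
published algorithm: the "h value" is realised as grayscale-reconstruction
peak prominence (a component containing two or more peaks of prominence
≥ h is split between them — but only when the component is compact, so
noise ripple along a streak cannot shatter a long track into spurious
short events), and "sharpness (image k-space distance)" as the fraction
of the component's above-threshold spectral energy beyond k-space radius
20 on the native frame grid (computed on a power-of-two patch with the
radius rescaled; by Parseval the fraction is patch-size invariant). Both
are isolated in single functions so alternates can be swapped.

Accepted counts accumulate on the binned grid (nearest pixel, half away
from zero) and are reported per cell as

$$\text{counts/min} = \frac{\sum_{\text{dilated mask}} \text{grid}}{t_{\text{live}}}
  \times 2^{\Delta t / T_{1/2}},$$

with $T_{1/2} = 110$ min for fluorine-18 and $\Delta t$ the time from
tracer calibration to acquisition start. Within-acquisition decay is not
corrected, live time (frames × exposure) is used rather than wall time
(dead time contributes no observation window), and the decay reference is
the timestamp of frame 0.

### Segmentation, dilation and merging

Cells are segmented from the phase image (threshold 0.1 rad, minimum area
50 µm²; both config-exposed since the reference protocol states neither),
with Sobel contours attached and labels assigned in reading order for
determinism. Each mask is dilated by a disc of one PSF sigma
(σ = 12.5 µm from the ~30 µm FWHM crystal response) so that counts
detected outside the cell footprint are still attributed to it. Cells
whose dilated masks intersect are all flagged merged and discarded — their
counts would cross-contaminate; for convex cells this is equivalent to an
edge gap below 2σ. Cells touching the image border are excluded as well
(their counts would be truncated); this is the package's own choice.

Grid registration: both grids share their physical origin at the top-left
pixel centre, so binned pixel $(i, j)$ is probed at full-resolution pixel
$(8i, 8j)$. The alternative "block-coverage" convention would shift
centres by 2.19 µm — far below the 30 µm RLM resolution — and the
shared-origin reading is used consistently everywhere.

### Statistics

Summaries are medians with type-7 (linear-interpolation) interquartile
ranges — the convention is recorded in the output since none is stated in
the reference analysis. Group comparisons use the two-tailed
Mann-Whitney-Wilcoxon test (exact null distribution for tie-free samples
of ≤ 10 total, normal approximation with tie and continuity correction
otherwise; the two-tailed p doubles the smaller tail, capped at 1) and
classical one-way ANOVA. The counts-vs-mass regression is Huber-weighted
IRLS: weighted least squares, residual scale re-estimated as the
normalised median absolute deviation, weights
$w_i = \min(1, c\,s/|r_i|)$ with the classical 95%-efficiency constant
$c = 1.345$ (the reference names Huber weights but no constant), iterated
to coefficient convergence. When all residuals are within $c\,s$ the fit
reduces exactly to ordinary least squares. Because it is unstated whether
the published adjusted $R^2$ came from the robust or the plain fit, the
package reports both (`adj_r_squared`, `adj_r_squared_ols`).

## What the generator emulates — and what it does not

The generator draws a phantom population with per-phase dry-mass medians
and IQR-derived log-spreads calibrated to the reference per-phase table
(G1 422 pg, G1/S 612 pg, S/G2/M 628 pg), phase mix (0.27, 0.19, 0.54, 0)
— chosen once from the absence of M/G1 cells in the reference data and a
typical HeLa proliferation index — and per-phase uptake medians equal to
the reference counts medians divided by the mass medians, so cycling cells
take up about twice as much tracer per cell as G1 cells while
mass-normalised uptake is nearly phase-independent. The per-cell uptake
multiplier has log-sd 0.30, set once so the simulated counts-vs-mass
regression reproduces the reference correlation structure (adjusted
$R^2 \approx 0.46$ at the median across seeds). Cell radius scales as the
cube root of mass around 11 µm at the reference mass; with the 633 nm
wavelength this gives peak phases near 6 rad, comparable to rounded HeLa
cells, and keeps the phase bandwidth within the carrier sideband.

Cells are rendered as truncated cosine caps (smooth profiles whose
amplitude inverts the mass integral exactly), placed by dart throwing with
a separation that keeps dilated boundaries disjoint by default. Phantom
activity is set analytically from the target counts/min: the expected
accepted-count rate equals activity × short-track fraction × the analytic
PSF capture fraction of the dilated disc × mean within-stack decay ×
decay-correction factor.

Ionisation-track shapes are *simulator knobs, not measured facts* — the
reference imagery shows short, long and diffuse morphologies but no
quantitative shape model. Defaults (75% short Gaussian spots of σ 0.6–1
binned px scattered with the 12.5 µm PSF; 15% streaks of 12–18 px, always
beyond the 10 px cutoff; 10% diffuse glows of σ 3.5–4.5 px at uniform
positions) are chosen so the published filter settings separate the
classes cleanly. EMCCD noise is additive read noise (σ 30 ADU) over a
baseline with a per-pixel fixed pattern (σ 20 ADU) shared with the dark
stack, so dark correction demonstrably raises SNR. Dead time (32%) is
modelled as readout gaps: it stretches wall time and isotope decay, not
live exposure.

Not emulated: optical diffraction and coherent imaging artefacts, EMCCD
gain-register statistics, scattering inside the crystal, cell motion,
bleed-through between fluorescence channels. Passing recovery tests on
this generator therefore shows the *processing* is faithful under the
stated acquisition model; it cannot certify behaviour on real microscope
data with artefacts outside that model.

## Numerical choices and degenerate inputs

* Carrier (0.4, 0.25) cyc/µm: integer cycles across the FOV (so the
  background fringes are exactly periodic), below Nyquist with the full
  sideband window inside the spectral half-plane.
* Carrier auto-detection excludes a small DC disc and one half-plane for
  determinism; an explicit failure is raised when the peak is not well
  above the median spectral magnitude (fringe contrast too low).
* Unwrapping is exact for residue-free fields; its output is re-anchored
  to the wrapped input by the median offset.
* Empty masks, NaN phase under a mask, geometry mismatches, merged cells
  passed to count integration, negative elapsed decay times, and constant
  regressors all raise immediate errors rather than propagating silently.
* IRLS convergence is declared at a relative coefficient change below
  1e-6 (cap 200 iterations); non-convergence is flagged in the result and
  warned about, never silent.
* Event-to-pixel assignment rounds half away from zero; coordinates are
  0-based pixel-centre throughout.

## Problem sizes used by the test-suite studies

The reference protocol records 20,000 frames of 20 ms (400 s live). The
package's simulated-study profile keeps the same 400 s of live exposure
regrouped as 2,000 frames × 200 ms — per-cell accepted-count statistics
are unchanged by the regrouping — and the 20-seed structural study in the
test suite uses 1,000 frames × 200 ms (200 s live), which roughly doubles
the per-cell Poisson spread of counts/min but leaves population medians
stable. Detector precision/recall is validated at the original 20 ms
exposure over 2,000 frames. `acq_config()`'s bare defaults remain the
full-scale protocol values.

## Known limitations

* The sideband window truncates the highest spatial frequencies of a
  cell's phase profile; masses are conserved to well under 1% for smooth
  cells, but the recovered phase at a sharp rim can be off by a few
  hundredths of a radian.
* The h-value and sharpness filters are reconstructions of an external
  algorithm's brief description; with other detector hardware their
  interpretation should be revisited (both are single swappable
  functions).
* The slope p-value of the robust fit uses the weighted-LS covariance of
  the final iteration, a standard but approximate choice at small n.
* One field of view per run; pooling across experiments is a plain table
  concatenation (`aggregate_tables()`), mirroring how the reference study
  pooled three experiments.
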
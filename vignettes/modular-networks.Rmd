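---
title: "Measuring modular correlation networks in developing cortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring modular correlation networks in developing cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modcor)
```

## The measurement problem

Before eye-opening, the visual cortex of carnivores generates spontaneous
activity that is *modular*: brief population events light up patchy
domains with a characteristic spacing of roughly 0.8 mm, and the domains
that co-activate form networks that span millimeters. `modcor` implements
the full chain of measurements used to characterize such networks in
widefield and two-photon calcium imaging — from raw fluorescence movies
to correlation-pattern statistics — together with a generator of
synthetic data on which every stage can be validated against known ground
truth.

This vignette explains the model behind each stage, the parameters that
matter, the numerical choices, and what the synthetic validation does and
does not establish about real data.

## Signal extraction

Widefield fluorescence is converted to ΔF/F₀ per pixel, where F₀ is a
sliding **rank-order filter**: the rank-70 sample (rank 190 for the
brighter, denser inhibitory-indicator signal) in a centred 30-s window of
451 samples at 15 Hz. A low order statistic tracks the slow trend of the
trace while ignoring positive transients. At the trace edges the window
is truncated and the rank rescaled proportionally (floored at 1); this
keeps the tracked quantile constant without padding artifacts. The window
is specified in samples and rescaled to the movie's frame rate (rounded
to the nearest odd integer) when rates differ. Whether the window is
centred or causal is a genuine choice; we use centred, which is phase
free.

Two-photon traces are neuropil-corrected as F_cell = F_raw − α·F_neuropil
with α = 0.6, baselined with a 60-s sliding median, and high-pass
filtered with a first-order Butterworth at 1/60 Hz. The filter is applied
forward–backward (`signal::filtfilt`), which squares the magnitude
response but eliminates phase lag; the tests verify >90 % attenuation of
a 600-s component, ≤10 % loss on a brief transient, and recovery to
within 1 % of zero within five time constants after a step.

Vessel pixels are excluded from all downstream statistics rather than
interpolated; interpolation would manufacture correlations at exactly the
spatial scales under study.

## Event detection

A pixel is active when it exceeds its own temporal mean by 3 s.d.
(2 s.d. for low-SNR indicators such as jRCaMP1a); active pixels must
belong to a contiguous region of at least 0.01 mm² (8-connectivity —
appropriate for smooth activity blobs); a frame is an event frame when
more than 50 % (30 % for low-SNR data) of valid ROI pixels are active.
Consecutive active frames form one event, split at any interior frame
that is a strict local minimum of the ROI-mean ΔF/F trace, with ties not
splitting: the ROI mean is the only scalar trace the detection rule
defines, and strictness makes the rule deterministic. Each event is
summarized by its maximally active frame. Datasets with fewer than 30
events are flagged and the pipeline refuses to run network analyses on
them.

The per-pixel threshold statistics are computed once over the whole
recording. This makes the detector's operating point depend on the event
*occupancy* (the fraction of frames inside events): if events fill much
more than ~10 % of the recording, the mean + 3 s.d. threshold rises into
the event amplitudes themselves and detection degrades. The synthetic
generator's defaults (4-frame events separated by 41 frames, ~9 %
occupancy) sit in the sparse regime the rule assumes.

## The synthetic generator

The generator is statistical, not biophysical. Each movie is built from:

- an orthonormal **pattern basis** of `n_basis` maps of band-limited
  spatial noise. Maps are produced by keeping the Fourier phases of white
  noise but equalizing the modulus onto a narrow Gaussian annulus
  (relative width 0.15) around a peak frequency calibrated — via the
  Hankel transform of the annular power spectrum — so that the
  angle-averaged autocorrelation has its first secondary peak exactly at
  the configured wavelength Λ. Two properties motivated this kernel over
  a broader difference-of-Gaussians band: (i) with the modulus equalized,
  every individual map realizes the calibrated autocorrelation, so the
  wavelength of a small basis is not at the mercy of spectral sampling
  noise (with Gaussian mode amplitudes the measured peak of an 8-map
  basis wandered by up to ±15 %); and (ii) a narrow band makes the
  measured scale insensitive to the spectral tilt of the 26/195 µm
  analysis band-pass, which shifts the apparent wavelength of an
  octave-wide band by 12–17 %. Anisotropy is an affine stretch of the
  annulus along a random axis.
- **events**: each event is a random Gaussian combination of the basis,
  scaled to unit spatial s.d., applied multiplicatively to a positive
  baseline field as F₀·(1 + g(t)·max(1 + 0.6·z, 0)) with a half-cosine
  envelope g; plus slow sinusoidal drift and white noise. The event
  amplitude (100 % ΔF/F at peak) and modulation depth (0.6) are
  calibrated so that the 3 s.d./50 %-area detection rules operate as
  intended — the quantities the generator must make meaningful, since no
  generative parameters are prescribed by the measurement definitions.
- **paired populations**: with alignment a ∈ [0, 1], the second
  population's events are a·(shared component) + √(1−a²)·(component from
  an independent orthogonal basis). Alignment 1 gives identical event
  weight draws; alignment 0 gives unrelated networks. Decorrelating only
  the *weights* on a shared basis would not do this: once the event count
  exceeds the basis size, both correlation tensors converge to the same
  basis-determined structure regardless of the weights, so network
  alignment must be controlled in pattern space.
- **cell populations**: cells at uniform random positions sample the
  shared modular field at their location (bilinear interpolation), with
  private noise and an additive shared neuropil trace whose gain matches
  the subtraction coefficient, so perfect subtraction is achievable and
  testable. E/I labels are independent of position.

Ground truth records basis, weights, spans, the generative wavelength and
the participation ratio of the weight covariance.

What the generator does *not* emulate: indicator kinetics beyond
gain/noise differences, hemodynamic artifacts, motion, vessel occlusion
patterns, non-stationary event statistics, and any mechanistic circuitry.
Passing tests therefore demonstrate that the estimators recover the
statistics they claim to measure on data satisfying their assumptions —
not that those assumptions hold in any particular recording.

## Correlation networks and their nulls

Event patterns are band-pass filtered (Gaussian blur difference,
σ_low = 26 µm, σ_high = 195 µm, mask-aware normalized convolution so ROI
boundaries and vessels do not bleed) and block-averaged to a coarser
grid; filtering precedes downsampling, and σ_high already provides
anti-aliasing. The correlation tensor C(s,·) is the Pearson correlation
across events between the seed pixel and every ROI pixel — computed for
all ROI seeds where feasible, or an even seed subsample for the
bootstrap loops (the statistic is a median over seeds; subsampling trades
only precision).

Surrogate ensembles destroy spatial alignment while preserving
single-pattern statistics: every event is independently rotated about the
ROI centroid (10° grid), translated (±450 µm on a 26 µm grid) and
reflected. Nearest-neighbour resampling is used so that pattern values
are moved, not smoothed — a bilinear null would be spuriously easy to
beat. Pixels mapped from outside the ROI are undefined, and a realized
surrogate stack keeps only pixels defined in *every* transformed event;
nearest-neighbour resampling is exactly value-preserving on the 90°
subgroup, which is what the invariance tests exercise. All bootstrap
p-values use the add-one estimator (k+1)/(n+1), which cannot report zero
from 100 surrogates.

## Spatial structure

**Fractures.** The rate of change of the correlation pattern per
micrometer of seed displacement, (1 − ρ(C(s,·), C(s′,·)))/dist over
4-neighbours, is dimensionally a 1/µm quantity and invariant to pattern
amplitude. Constant-pattern tensors (zero variance across pixels) are
assigned zero rate rather than NaN. Line extraction follows median
filtering (78 µm window), CLAHE (clip limit 20, 260 µm tiles, 256 bins),
Gaussian high-pass (σ = 390 µm), binarization at zero, one erosion and
two dilations with a 3×3 box, and Zhang–Suen skeletonization. Fracture
magnitude is computed from the *raw* strength field using the
CLAHE-derived lines (mean on lines minus mean at pixels >130 µm from any
line): CLAHE equalizes contrast and would distort the magnitude's scale
if measured after it. Note the erosion step removes ridges thinner than
three pixels; at 26 µm pitch this is a ~78 µm minimum fracture width.

**Wavelength.** Seed-centred correlation neighbourhoods (1500 µm radius)
are averaged across seeds, angle-averaged in radial bins one pixel pitch
wide, and smoothed with a cubic smoothing spline under generalized
cross-validation; the wavelength is the radius of the first strict local
maximum after the initial descent. Profiles without a secondary maximum
are flagged undefined rather than extrapolated.

**Eccentricity.** The innermost closed 0.7 iso-contour around the seed
(marching squares with linear interpolation) is fitted with a direct
least-squares ellipse; ε = √(ς₁²−ς₂²)/ς₁. Contours cut by the ROI
boundary are excluded from summaries — an open contour fit would bias ε
upward. Note that isotropic *generators* still yield median ε well above
zero: each seed's local correlation bump is a finite sample of
quasi-periodic structure and is individually elongated at random
orientation; ε measures that local elongation, not global anisotropy.

**Domains.** Local maxima of each band-passed event (3×3 neighbourhood,
positive values, 400 µm minimum separation) are fitted within a 600 µm
disk by a 7-parameter rotated Gaussian (Levenberg–Marquardt). The
orientation is initialized from second moments; because an exactly
axis-aligned start makes the rotation gradient degenerate, jittered
restarts are attempted on failure. (σx, σy, θ) is identified only up to
an axis swap with a 90° rotation; widths are therefore reported as
minor/major. Fits are rejected when the optimizer fails, the amplitude is
non-positive, or the centre drifts more than half the fit radius. Domain
size is FWTM = 2σ_minor√(2 ln 10); FWTM/FWHM = √(ln 10/ln 2) ≈ 1.8226 is
a parameter-free identity the tests check on every fit.

## Dimensionality and E/I similarity

d_eff = (Σλ)²/Σλ² is computed from the N×N event Gram matrix of
mean-centred patterns, which shares the pixel covariance's nonzero
spectrum at a fraction of the cost. The sample participation ratio is
biased low by ≈ (d+1)/N for d comparable to N — hence the reported
median over 100 random 30-event subsamples, which makes values
comparable across recordings with different event counts, and hence the
10 % (not 5 %) recovery tolerance used for d = 16 at N = 200.

Similarity between two networks is the per-seed Pearson correlation of
their C maps over shared pixels beyond an exclusion radius (400 µm
default, swept to 1400 µm), aggregated by the median over seeds (medians
match the robust-summary convention used throughout). Its ceiling under
finite sampling is estimated by 100 random half-splits of one
population's events; because the halves have N/2 events each while the
between-population comparison has N per side, an aligned pair can
legitimately *exceed* the split-half band, so the validation requires
aligned similarity at or above the band's lower bound. Significance is
assessed against surrogate tensors of the comparison population.

## Cellular scale

Population event frames are frames where >10 % of cells exceed their mean
by 2 s.d.; activity on those frames is z-scored across cells per frame,
and pairwise cellular correlations are computed over event frames.
Matched-set E/I similarity pairs every inhibitory cell with its nearest
excitatory cell within 50 µm, correlates each seed cell's correlation
vector onto the I set against the matched-E set beyond a 200 µm
exclusion, and tests the median against 100 pairing shuffles. Local
event amplitude averages each type's z-scored activity within 75 µm of a
cell at each event's maximally active frame (the frame of maximal
population-mean z within the block); the seed cell is excluded from its
own type's average to avoid self-correlation inflation. The co-driven vs
independent-drive contrast in the local E/I amplitude correlation has an
event-limited sampling scale of ~1/√(n_events) — pairs share events — so
null-calibration runs use hundreds of events, not hundreds of pairs.

## Problem sizes and determinism

The default validation configurations are desk-scale: widefield movies of
96×96 pixels at 52 µm (a 5 mm field, large enough to hold the
1.8–2.2 mm test band), 128×128 at 26 µm for detector checks, 40–60
events, 100 surrogates and 100 resampling repetitions, and two-photon
populations of ~100 cells over 1200 µm. These sizes keep every
distributional test well-posed while an end-to-end run completes in
minutes. All randomness flows from explicit seeds: identical
configuration and seed give bit-identical movies, ensembles, and summary
files.

## Known limitations

- The fracture-strength formula is a reconstruction of "rate of change of
  the correlation pattern" — a reasonable, amplitude-invariant choice in
  1/µm units, but other discretizations are defensible.
- CLAHE tiling is rounded to whole pixels; on small grids the effective
  tile geometry quantizes coarsely.
- The surrogate value-multiset property holds exactly only for the
  bijective transform subgroup; general rotations resample a few pixels
  twice.
- The generator's narrow spectral annulus makes patterns more strictly
  quasi-periodic than real cortical activity, which has broader spatial
  bandwidth; wavelength recovery on real data will carry the analysis
  filter's tilt as an additional (small) systematic.
- No motion correction, cell segmentation, or spike inference: inputs are
  assumed registered, and cellular ROIs are given.
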
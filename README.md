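# modcor

Analysis of large-scale modular spontaneous activity in calcium imaging of
the developing visual cortex, for researchers characterizing correlated
network structure before eye-opening: widefield ΔF/F extraction, detection
of spatially extended spontaneous events, seed-point correlation networks
with surrogate-pattern null models, correlation fractures, modular
wavelength, local eccentricity, active-domain size, participation-ratio
dimensionality, excitatory-vs-inhibitory network similarity, and
cellular-resolution (two-photon) correlation analyses. A synthetic-data
generator with known ground truth drives validation of every stage.

## The quantities at the core

Given N detected events with band-pass filtered maximal-frame patterns
A_i, the **seed-point correlation pattern** for seed pixel s is the
Pearson correlation across events,

    C(s, x) = (1/(N−1)) Σ_i [A_i(s) − ⟨A_i(s)⟩][A_i(x) − ⟨A_i(x)⟩] / (σ_s σ_x),

computed for every ROI pixel x. On top of C the package measures:

- **Long-range strength** — median C at correlation maxima 1.8–2.2 mm from
  the seed, tested against 100 surrogate ensembles in which every event is
  independently rotated (0–350° in 10° steps), shifted (±450 µm in 26 µm
  steps) and reflected; p-values use the add-one bootstrap estimator
  (k+1)/(n+1).
- **Fractures** — strength(s) = mean over adjacent seeds s′ of
  [1 − ρ(C(s,·), C(s′,·))]/dist(s,s′), in 1/µm; fracture lines via median
  filter → CLAHE → Gaussian high-pass → binarize → erode/dilate →
  skeletonize, and fracture magnitude as the on-line vs far-field
  (>130 µm) strength difference.
- **Wavelength** — radius of the first secondary peak of the seed-centred,
  angle-averaged correlation profile (spline-interpolated).
- **Eccentricity** — ε = √(ς₁²−ς₂²)/ς₁ of the least-squares ellipse fitted
  to the C = 0.7 iso-contour around the seed.
- **Domain size** — FWTM of the minor axis of a rotated 2D Gaussian fitted
  to each activity domain: FWTM = 2σ_minor √(2 ln 10).
- **Dimensionality** — participation ratio d_eff = (Σλ_i)²/Σλ_i² of the
  event-covariance spectrum, median over 100 subsamples of 30 events.
- **E/I similarity** — per-seed second-order Pearson correlation between
  two populations' C maps, excluding pixels within 400–1400 µm of the
  seed, with split-half upper bounds and surrogate nulls.

## Worked example

```r
library(modcor)

cfg <- synth_config(grid_height_px = 96L, grid_width_px = 96L,
                    pixel_size_um = 52, wavelength_um = 800, n_events = 40L)
sim <- synthesize_movie(cfg)               # movie + ground truth
dff <- compute_dff(sim$movie)              # rank-order baseline, dF/F
es  <- detect_events(dff)                  # 3 s.d., 0.01 mm^2, 50 % rules
n_events(es)
#> [1] 40
st  <- bandpass_and_downsample(es)         # 26/195 um band-pass
tz  <- correlation_tensor(st)
correlation_wavelength(tz)$wavelength_mm
#> [1] 0.793
effective_dimensionality(st)$d_eff
#> [1] 7.046459
lr <- long_range_strength(correlation_tensor(st, seed_subsample(st, 120)),
                          make_surrogates(st, n = 100, seed = 2))
c(lr$statistic, lr$p)
#> [1] 0.75337217 0.00990099
```

The detector recovers all 40 implanted events; the wavelength estimate
(0.793 mm) matches the 0.8 mm generative wavelength; d_eff ≈ 7 for 40
events drawn from an 8-pattern basis (the sample participation ratio is
biased low by roughly (d+1)/N); and the long-range correlation statistic (0.75)
far exceeds every one of the 100 surrogates (p = 1/101), as expected for
modular activity spanning a 5 mm field.

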
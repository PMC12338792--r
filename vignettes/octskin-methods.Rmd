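---
title: "Methods: OCT-derived skin thickness and attenuation in longitudinal photodamage studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OCT-derived skin thickness and attenuation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`octskin` quantifies photodamage-related change in skin from volumetric
optical coherence tomography (OCT). From a log-scale intensity volume it
derives, per averaged A-scan, (i) the combined epidermis+dermis thickness and
(ii) the dermal attenuation coefficient, aggregates both to per-volume means,
and runs a longitudinal four-group comparison plan (control, UVR control,
UVR + NMN, UVR + PL across back/side/stomach imaging sites). Because the kind
of mouse imaging data this targets is not generally available, the package
includes a first-class synthetic generator: a four-layer skin phantom with
known interface depths and dermal attenuation, so that every downstream stage
can be validated against ground truth.

# The phantom

An A-scan is modelled on a depth grid $z_i = i\,\Delta z$ (default
$\Delta z = 4\,\mu m$; the emulated instrument acquires 1355 A-scans per
B-scan and 120 B-scans over 6 × 6 mm at 4.4 µm lateral spacing). Within each
layer the mean linear amplitude follows single-scattering Lambert–Beer decay,

$$A(z) = A_0 \exp\left(-\mu\,(z - z_\mathrm{top})\right),$$

with per-layer reflectivity $A_0$ and attenuation $\mu$ (mm⁻¹). Defaults:
air standoff 100 µm at the noise-floor amplitude; epidermis 20 µm,
$\mu = 15$ mm⁻¹; dermis 400 µm with $\mu$ the parameter of interest
(40 mm⁻¹ baseline-like, ~25 mm⁻¹ UVR-like, spanning the 20–45 mm⁻¹ range
such studies report); muscle rendered as a flat plateau (see below). Each
tissue interface carries a one-pixel specular reflection of twice the
underlying layer reflectivity, giving peak detection a well-defined "first
peak" (surface) and "second peak" (dermal–epidermal junction, DEJ).

Speckle is multiplicative on linear amplitude: unit-mean gamma draws with
shape $k$ (default 16, emulating effectively multi-look averaged export
data; $k = \infty$ disables noise). Unit mean preserves the expected
exponential decay, so averaging leaves the attenuation fit unbiased.
Intensities are stored as natural-log amplitude; the volume's `scale` field
records the convention (`"db"` is also supported by the fitting code).

Interfaces receive independent smooth lateral jitter fields (iid Gaussian on
a coarse grid, bilinearly upsampled, sd = `thickness_jitter`, default 10 µm,
truncated at 4 sd). Layer order is preserved by minimum gaps (8 µm
epidermis, 40 µm dermis). Ground truth records the realized per-position
interface depths and `skin_thickness = muscle_depth - surface_depth` exactly.

The phantom deliberately omits: confocal/focal-plane effects and the
instrument's multi-beam focus merging, sensor roll-off, multiple scattering,
and any lateral point-spread function. Consequences are discussed under
*What passing tests show*.

# Preprocessing and calibration

Each B-scan is block-averaged along the lateral axis on the stored log
scale: column $j$ of the output is the mean of raw columns
$[(j-1)w + 1,\ \min(jw, n)]$ with window $w = 10$. The trailing partial
block is kept — this is the only convention under which 1355 raw columns
yield 136 averaged columns and, after trimming 15 low-intensity columns from
each edge, the published counts of 106 usable averaged A-scans per B-scan
and 12,720 per volume. A window wider than the B-scan yields one column
rather than an error.

Calibration pools annotated air and muscle regions over a set of reference
volumes (by default one baseline volume per group):

* `air_mean` — the noise floor; only peaks above it are considered.
* `muscle_mean` — the global threshold for the dermis–muscle boundary.
* `prominence_threshold` — the original analysis set this "experimentally";
  the package uses a reproducible surrogate,
  $\max(4.5\,\hat\sigma_\mathrm{air}/\sqrt{w},\ 0.1)$, where
  $\hat\sigma_\mathrm{air}$ is the (population) sd of air-region log
  intensity. The $\sqrt{w}$ factor matches the threshold to the noise scale
  of the *averaged* columns that are actually searched. The multiplier was
  chosen by a designed threshold scan on synthetic reference volumes:
  3 standard errors let spurious air-noise peaks usurp the "first peak"
  (segmentation validity 0.42, ~1% wrong surfaces), while the raw-voxel
  3-sd rule (≈0.76 log units) rejected interface peaks weakened by block
  averaging across a jittered interface (validity 0.76). At 4.5 standard
  errors (≈0.36 log units) validity is ≈0.9 with no observed surface
  errors. The floor of 0.1 keeps the threshold positive for noiseless data.

# Segmentation

Per averaged A-scan:

1. **Surface** — first local maximum above the noise floor with topographic
   prominence ≥ threshold. Plateau ties resolve to the shallowest index
   (deterministic, identically biased across groups).
2. **DEJ** — the second such peak.
3. **Dermis–muscle boundary** — the first sample deeper than the surface at
   which intensity drops strictly below `muscle_mean`. The search begins
   only once the profile has descended `prominence_threshold` below the
   surface-peak value; applied naively, the global threshold would trigger
   in the dark epidermal trough just under the surface peak.

A column is *valid* only if all three indices exist in increasing depth
order. Invalid columns are excluded from volume means rather than imputed,
and `n_valid / n_total` is reported for quality control. Thickness is the
optical path `(muscle_idx - surface_idx) * axial_pitch`; an optional
refractive-index divisor exists but defaults to 1 (off), since log-image
pipelines of this kind typically report optical distance.

A geometric point that shaped the phantom defaults: a *global* muscle-mean
threshold lands at the dermis–muscle interface only if it sits strictly
between the dermis base signal and the muscle-level signal. In a phantom
whose muscle decays, the region mean is crossed mid-region, not at the
boundary. The default phantom therefore renders muscle as a flat plateau,
and the synthetic muscle annotation starts two pixels above the shallowest
muscle interface, so the pooled region mean includes the bright interface
line and sits just above the plateau. With that geometry the noiseless
boundary is found within one pixel everywhere, and speckled volume means
land within two axial pitches of truth. On real data this corresponds to
annotating the muscle band inclusive of its top boundary; the paper-style
rule remains sensitive to how that region is drawn, which is a genuine
limitation of global thresholding (boundary contrast also degrades as
photodamage progresses).

# Attenuation fitting

Under the single-scattering model the dermis is linear in the log domain,
so an ordinary least-squares line over the DEJ-to-boundary region of
interest estimates $-\mu$ directly on natural-log amplitude, or
$-\mu\,\ln 10/10$ per stored dB. No round-trip (factor 2) correction is
applied: values are reported under the same single-pass convention as the
studies whose 38–45 mm⁻¹ baseline range the phantom emulates. A
configuration note rather than a claim: the absolute scale of such μ values
carries a log-convention caveat; group *contrasts* do not.

The ROI excludes 1 pixel at the DEJ end and 2 pixels at the boundary end by
default (`roi_trim`). The interface pixels are specular reflections, not
dermal scattering; a single spike point at an ROI end leverages the slope
by ~0.1–1.5 mm⁻¹ and would make exact noiseless recovery impossible. With
the trims, noiseless phantoms recover μ to machine precision and full-size
speckled phantoms to ≲0.1%. Fits shorter than `min_points` (default 5; a
2-point fit is exact but meaningless) are flagged invalid and excluded, as
are whole columns without a valid segmentation. Plain OLS is used — no
weighting for the heteroscedastic speckle, matching the method being
reproduced.

# Group statistics

The comparison plan mirrors the study design, per metric and site:

* one-way ANOVA across the four groups at baseline and at month 7
  (classic equal-variance F; the degenerate all-identical case is defined
  as p = 1, zero within-variance with unequal means as p = 0);
* Mann–Whitney U follow-ups *only* where the month-7 ANOVA p < α (0.05):
  each group baseline-vs-month-7 (4), control vs each UV-exposed group (3),
  UVR control vs each treated group (2) — unpaired throughout, as mouse
  replacement breaks pairing;
* IQR outlier removal before the Mann–Whitney tests only, per
  group × site × month cell: fences at Q1 − 3·IQR and Q3 + 3·IQR with
  type-7 (linear interpolation) quartiles — the standard reading of
  "3 times the IQR"; removed counts are reported;
* raw two-sided p-values, no multiple-testing correction, matching the
  reporting style being reproduced.

The Mann–Whitney p is exact (null enumeration) for tie-free samples with
$n_a n_b \le 400$ and otherwise uses the normal approximation with tie and
continuity corrections; identical samples sit at the null centre and give
p = 1. The test suite checks the exact path against full label enumeration
for all $n_a, n_b \le 5$ and the F statistic against explicit sums of
squares.

`longitudinal_summary()` reproduces the monthly-mean + trend-line view:
group × site × month means and an OLS slope of those means against month.

# The synthetic study and what passing tests show

`run_simulate()` writes a full study to disk: one phantom volume per
(mouse, group, site, month), with per-mouse true attenuation and thickness
drawn around group trajectories (`study_effect_profile()`): attenuation
starts at 41.5 mm⁻¹ everywhere and declines linearly to 22–27 mm⁻¹ in
UV-exposed groups by month 7; thickness starts at 420 µm and grows by up to
120 µm; the back receives the full effect, the side 60%, the stomach 20%;
between-mouse sd 3 mm⁻¹ / 25 µm. These values were fixed once, inside the
ranges the emulated study reports, and are not fitted to anything.

Operating characteristics of the plan (type-I rate of the ANOVA gate, power
of the follow-ups at a planted Δμ = 10 mm⁻¹, n = 6/group) are estimated on
the metric-level generator `simulate_metric_series()` — group trajectory +
mouse effect + per-volume measurement noise of 0.5 mm⁻¹, an upper bound on
the estimation error measured from full phantom runs (≲0.1 mm⁻¹ at
12,720 averaged A-scans). Running hundreds of replicates of 144 full
volumes would add nothing but the same measurement noise at far greater
cost; one reduced-size end-to-end volume run exercises the full path. The
problem sizes used by the tests and the acceptance script are: full
1355 × 120 volumes for recovery checks (single volumes per μ value),
reduced volumes (≤200 × 10 A-scans) for unit tests, 200 replicates for the
null rate and 100 for power.

Passing these tests shows that the *pipeline machinery* is correct under
the stated phantom assumptions. It does not show that the method is
accurate on real mouse skin: the phantom has no multiple scattering (which
biases single-scattering μ estimates), no focal-plane or roll-off effects,
a cleaner muscle boundary than photodamaged skin exhibits, and gamma
speckle that is tamer than fully developed speckle. Absolute μ accuracy on
real data also depends on the instrument's undocumented log scaling.

# Numerical and design choices

* Axial pixel pitch 4 µm is a free simulator parameter — the emulated
  instrument documents a 5.5 µm axial *resolution*, not a pitch.
* On-disk formats: multi-page TIFF (one page per B-scan) with 32-bit
  samples on a fixed affine [0,1] mapping (storage precision ~2 × 10⁻⁸ log
  units; round-trips are exact to metadata and to <10⁻⁶ in intensity), a
  JSON sidecar carrying shape, pitches, scale and provenance (missing
  fields are errors, not defaults), JSON region annotations with 0-based
  half-open bounds, CSV study tables with closed group/site vocabularies.
  In memory, R's ordinary 1-based inclusive indexing is used; conversion
  happens only at the I/O boundary.
* Determinism: every volume is generated from a single RNG stream seeded by
  `PhantomSpec$seed`; `run_simulate()` derives per-volume seeds from the
  master seed below 2³¹; the ambient RNG state is restored after use.
* Averaging operates on stored log values (matching a linear fit performed
  on log-scale images); linear-domain averaging is available as a
  sensitivity switch in the phantom but is off by default.

# Limitations

Global-threshold boundary detection degrades when dermis and muscle optical
properties converge; no depth-resolved (per-pixel) attenuation, no extended
Huygens–Fresnel modelling, no epidermis/dermis split (the epidermis spans
only 2–5 pixels at this pitch), and no mixed-effects longitudinal
modelling — the plan intentionally reproduces an unpaired, per-comparison
analysis.
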
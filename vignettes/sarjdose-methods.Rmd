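---
title: "Models and methods behind sarjdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sarjdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarjdose)
```

`sarjdose` supports the dosimetric commissioning of a shielded jig that
irradiates flank tumours in mice with parallel-opposed tangential
kilovoltage beams inside a cabinet irradiator. This vignette is the
package's own account of the models it implements, the parameters that
matter, and what its synthetic-data tests do and do not demonstrate.

## Film calibration

Radiochromic film darkens with dose; scanned 24 h after exposure at
600 dpi in 48-bit RGB, its red channel carries the dosimetric signal. A
Hunter–Driffield standard curve relates mean red-channel pixel value
(16-bit scale, 0–65535) to absorbed dose.

**Fit direction.** Film calibration is usually plotted as pixel against
dose, but the quantity needed in analysis is dose given pixel. The two
views carry identical information for a monotone response, so
`build_hd_curve()` fits dose `= P(pixel)` directly by ordinary least
squares — converting a measurement is then a single polynomial evaluation
with no numerical inversion. The fitted mapping must be strictly monotone
over the calibrated pixel span (checked on a 1000-point grid); a
non-monotone fit is rejected as an unusable calibration rather than
silently accepted.

**Order.** The caller supplies order 3 or 4, as different experiments
favour different orders; `order = "auto"` picks the order with the
smaller leave-one-out RMS prediction error, an unbiased small-sample
criterion that needs no held-out data.

**Extrapolation policy.** Film saturates outside its dynamic range
(RTQA2: 0.02–8 Gy; EBT-XD: 0.1–60 Gy), so `dose_from_pixel()` refuses
pixel values outside the calibrated span rather than extrapolating. A 1%
guard band (configurable) admits benign noise at the span edges; doses
landing outside the calibrated dose range there are clipped to it and
flagged. An unexposed 0 Gy point is always accepted in calibration sets
even though it sits below the films' nominal dynamic range, because it
anchors the unexposed end of the curve; the dynamic-range validation
applies to positive doses.

**Residual metric.** `fit_residual` is the RMS *relative* residual over
positive doses. It is dominated by the low-dose end, where any
polynomial's relative error is largest; it is a comparability metric
between curves, not an accuracy guarantee at a given dose.

**Inter-experiment deviation.** `curve_set_deviation()` expresses each
experiment's pixel value at a dose as percent deviation from the
cross-experiment mean, excluding doses measured by fewer than three
experiments (sparse doses make the "mean curve" itself unreliable). The
deviations at each dose average to zero by construction.

## Film images and dose maps

Scans are handled in (row, column) raster coordinates, 0-based math on
1-based R indices, row 1 at the top; positions convert to mm through
`mm_per_pixel = 25.4 / dpi`. 8-bit inputs are accepted and rescaled by
257 with a warning. Plain TIFF files written by this package carry no
resolution tag, so rendered films ship with a JSON sidecar holding the
dpi and film model; `load_scan()` reads TIFF metadata, the sidecar, or an
explicit override, and errors when none is available rather than guessing
a spatial scale.

`dose_map()` converts pixelwise and **masks** out-of-span pixels instead
of clipping them. Two deliberate choices protect low-dose (shielded
region) statistics from bias:

- In-span per-pixel doses are *not* clipped at the 0 Gy floor. Around an
  unexposed level, symmetric pixel grain converts to small positive and
  negative doses; clipping the negatives would bias every regional mean
  upward by a substantial fraction of the leakage signal itself.
- `profile_from_scan()` implements the readout used for films in
  practice: average pixel values over a region first, convert the mean
  once. Converting pixelwise and averaging doses is biased near the
  unexposed end both by masking (grain pushes single pixels beyond the
  calibrated span, truncating one tail of the distribution) and by the
  curvature of the dose-of-pixel polynomial acting on per-pixel noise.
  The pixel-space readout has neither problem and is the right tool for
  leakage floors; the pixelwise dose map remains the right tool for
  in-field work, where sensitivity is high and both biases are
  negligible.

## Profile analytics

Profiles are normalised to percent of a plateau mean (window
configurable; default the central fifth of the profile). Level crossings
(80/20% for penumbra, 50% for field edges) are found by walking outward
from the plateau and linearly interpolating between the first bracketing
samples, which is robust to plateau noise. The 80–20% penumbra of an
error-function edge with spread σ has the closed form
(z₀.₈ − z₀.₂)·σ ≈ 1.683σ, the oracle used throughout the tests.

The margin-offset sign convention is: positive = exposure edge on the
tumour (in-field) side of the margin, negative = spill into the shielded
side. The in-field side is inferred from which 50% crossing lies nearest
the margin.

Restraint-to-restraint uniformity reports both SEM% and maximum absolute
deviation from the mean, because both conventions are in common use and
they answer different questions (precision of the mean vs worst-case
site); they are never conflated.

The flatness window defaults to the central 80% of the 50%-edge field
width. For a 10 mm field with ~2 mm penumbrae this window reaches the
penumbra shoulder, so flatness values of tens of percent are expected
geometry, not an error; narrow the `core_fraction` for sharper fields.

## Jig physics

The analytical model is deliberately simple and self-consistent:

- **Shielding**: *n* HVLs transmit 2^(−n). The lead HVL at this beam
  quality (225 kV, 0.5 mm Cu added filtration) is not a tabulated input
  but derived from the jig's own specification that 2.1 mm of lead is
  three HVLs: 0.7 mm. The restraint plus the 3.0 mm roof gives
  5.1 mm / 0.7 mm ≈ 7.3 HVLs, i.e. sub-1% narrow-beam transmission.
  Measured shielded-site doses in broad-beam conditions exceed this
  because of scatter; the model carries a single additive
  `scatter_fraction` (default 0) and does not attempt to resolve scatter
  physics.
- **Depth dose**: a single effective exponential,
  D(z) = D₀·e^(−μ_eff·z), with no build-up or scatter kernel. The default
  μ_eff = 0.0207/mm makes the drop across half of a 7 mm tumour exactly
  7.0%, the centre of the 5–10% entry-to-midline band such tangential
  set-ups exhibit; tissue-equivalent attenuation at these energies is of
  this order.
- **Parallel-opposed summation**: each of two equally weighted opposed
  beams needs entry dose (Rx/2)·e^(+μt/2) for the pair to sum to Rx at
  the midline. Because the two single-beam gradients are antisymmetric
  about the midline, the summed profile is flatter than either beam — the
  mechanism by which opposed tangents cut site-to-site dose variability
  roughly in half.
- **Beam asymmetry**: the 195° tangent delivers a ~7% lower dose rate
  than the 15° tangent (a measured, geometry-driven ratio, default 0.93
  in the configuration); equal per-beam doses are restored by scaling its
  beam-on time by 1/0.93. No angular dose dependence beyond this ratio is
  modelled.
- **Inverse square**: dose rate scales with (d_ref/d)²; the conserved
  product rate·d² is a test invariant.

## Treatment analysis

Tumour volume uses the standard flank-tumour formula V = W²L/2. Growth
summaries follow the surviving-animals convention: an animal stops
contributing after its event day (no last-observation carry-forward), so
late-day group means describe the animals actually alive then — a source
of survivor bias that any reader of such curves should keep in mind, but
the convention used in this setting.

Survival uses the Kaplan–Meier product-limit estimator (via
`survival::survfit`). Humane-endpoint euthanasia is an event; reaching
the day-35 study end alive is censoring.

`rank_sum_exact()` computes the Mann–Whitney U and an exact two-sided
p-value by full enumeration of all C(n₁+n₂, n₁) group labelings of the
pooled sample (bounded at combined n = 20). Ties are handled with
midranks under the permutation null over the observed values, so the
p-value stays exact under ties — which `stats::wilcox.test`'s exact path
cannot do. Extremeness is measured as |U − n₁n₂/2|; for tie-free data
this equals the classical double-tail exact p, which the tests verify
against `wilcox.test`. Per-day comparisons are exploratory and reported
without multiplicity adjustment, labelled as such.

## Synthetic data: what it emulates and what it does not

Every generator returns its ground truth with the data, and every
recovery test compares estimates against that returned truth.

**Film response.** The forward model pixel(dose) is a fourth-order
polynomial fitted to an exponential-saturation anchor curve falling from
58000 (unexposed) to 12000 over the film's range, with time constant
one third of the maximum dose (20 Gy for EBT-XD); strict monotonicity is
verified on a fine grid. Noise has three physically distinct components:

- per-sheet batch offset, SD 2.5% — the scale of inter-experiment
  calibration variability; absorbed by per-sheet calibration exactly as
  in real practice (calibration and measurement film from the same
  sheet);
- per-point noise on calibration mean pixels, SD 0.1% — a calibration
  point is a 50×50 ROI mean, so its grain-driven standard error is the
  per-pixel grain divided by 50 (0.02% at 1%/pixel), plus film-piece
  non-uniformity;
- per-pixel grain in rendered images, SD 1%.

**Beam fields** are separable erf-edged rectangles over a uniform
leakage floor. The default edge spread σ = 1.188 mm is calibrated so the
analytic 80–20% width is 2.0 mm — matching a printed summary figure for
such jigs, not a measured profile — and the default leakage fraction
0.008 is the 7-HVL narrow-beam level.

**Phantom exposures** evaluate the analytical jig model at the six
instrumented sites (tumour dorsal/mid/ventral from each beam; shielded
head/body/rear); they inherit all of that model's simplifications.

**Tumour growth** is exponential with per-fraction multiplicative cell
kill, a post-treatment growth arrest, and per-animal lognormal rate
heterogeneity. Defaults: V₀ = 256 mm³ (an 8×8 mm day-8 tumour through
W²L/2), rate 0.22/day (an untreated tumour reaches a 1000 mm³ humane
endpoint about six days after day 8), kill fraction 0.7 per fraction on
days 8–10, 10-day regrowth delay (treatment response of about ten days
before recurrence), measurement every 2 days to day 35 with 5% calliper
noise.

What passing these tests shows: the estimators recover known truth
through the full measurement chain at realistic noise scales, with the
documented tolerances. What they do not show: agreement with any real
scanner's colour management, real film's darkening kinetics or lateral
response, broad-beam scatter, or real tumour biology. Measured film
results from a physical jig (restraint SEM, margin offsets, shielded-site
doses) are descriptive of those films and are not reproducible without
them; the package validates the *methods* against synthetic ground
truth.

## Numerical choices and problem sizes

- Polynomial fits use raw (not orthogonal) polynomial bases so
  coefficients are directly interpretable and serialisable; fitted
  mappings are evaluated from the increasing-power coefficient vector.
- Monotonicity checks use 1000-point grids; crossing searches interpolate
  linearly between samples (interpolation error is second-order in the
  sample spacing, ~0.04 mm at 600 dpi).
- The exact rank-sum enumeration is bounded at combined n = 20
  (184 756 labelings at 10+10) — comfortably covering preclinical group
  sizes; larger samples belong with asymptotic tests.
- Test and validation problem sizes: 600-dpi renders of ~13×13 mm fields
  (≈ 615×615 px), nine replicate calibration curves, 100–200-replicate
  Monte-Carlo property checks, six animals per group over 28 days. These
  sizes keep every statistic's Monte-Carlo error well below the
  tolerance it is tested against.
- Bit-reproducibility: every stochastic generator takes one explicit
  seed and restores the caller's RNG state afterwards.

## Known limitations

- The depth-dose model has no build-up region; at 225 kV build-up is
  sub-millimetre, but surface doses are approximate.
- Scatter at shielded sites is a single additive fraction, not a model;
  measured shielded doses under broad beams will exceed the narrow-beam
  prediction.
- The film forward model is one plausible monotone response; real
  batch-to-batch curve *shape* changes (not just offsets) are not
  emulated.
- `margin_offset()` assumes a single threshold crossing near the margin;
  pathological profiles (multiple islands) report the nearest crossing.
- Growth simulation treats fractions as instantaneous volume reductions;
  radiobiological dose-response (LQ models, repopulation kinetics) is out
  of scope.
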
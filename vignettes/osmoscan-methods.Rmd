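---
title: "Methods: osmoscan index extraction and cohort simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: osmoscan index extraction and cohort simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The assay and its indices

Osmotic-gradient ektacytometry (the "osmoscan" mode of a laser-diffraction
ektacytometer such as the Lorrca MaxSis) shears a dilute red-cell suspension
in a Couette viscometer at constant shear stress (30 Pa, 37 °C) while the
extracellular osmolality is swept from 0 to 500 mOsm/kg. The recorded
elongation index (EI) — the normalized axis ratio of the diffraction
pattern — traces a characteristic curve: a small sub-lysis bump, a fall into
a hypoosmotic valley, a rise to the deformability maximum near isotonicity,
and a slow hyperosmotic descent. Seven indices summarize it:

| Index | Definition | Units |
|---|---|---|
| `O_min`, `EI_min` | position and depth of the hypoosmotic valley (linked to 50% osmotic lysis) | mOsm/kg, — |
| `O_EI_max`, `EI_max` | position and height of the EI maximum | mOsm/kg, — |
| `O_hyper` | osmolality on the descending arm where EI falls to `EI_max / 2` (a cell-hydration marker) | mOsm/kg |
| `EI_hyper` | `EI_max / 2` by definition | — |
| `Area` | trapezoidal area under the curve between `O_min` and `O_hyper` | mOsm/kg |

The package implements (i) extraction of these indices from raw curves with
QC flagging, (ii) a synthetic curve generator whose ground-truth indices are
exact inputs, (iii) simulators for a healthy-donor cohort and red-cell
density fractions, (iv) the statistical pipeline (normality-gated paired
tests, linear models, percentile reference intervals), (v) morphometry of
labeled segmentation masks, and (vi) the small marker computations
(gravimetric water fraction, band 4.1a:b densitometry, geometric-mean
fluorescence).

## The synthetic curve model

No public functional form exists for an osmoscan trace, and the instrument's
raw data are not redistributable. The generator therefore *defines* the
noiseless curve as monotone piecewise-cubic Hermite segments through the
named control features:

```
(start_osm, 0) --> (bump_osm, bump_ei; slope 0) --> (O_min, EI_min; slope 0)
  --> (O_EI_max, EI_max; slope 0)
  --> descending monotone cubic through (O_hyper, EI_max/2) and (500, end_ei)
```

Free interior slopes use the Fritsch–Butland harmonic mean with the
Fritsch–Carlson limiter, so every segment is provably monotone; fixed slopes
that would break monotonicity raise a construction error naming the segment.
Because the half-maximum point is an interpolation knot, `EI(O_hyper) =
EI_max / 2` holds exactly, and every target index is an explicit generator
input. That makes the generator a clean oracle: extraction can be validated
by round trip against known truth rather than against hand-picked expected
values. The ground-truth `Area` is a fine-grid (8192-point) trapezoidal
quadrature of the noiseless shape between `O_min` and `O_hyper`.

Noise is additive homoscedastic Gaussian on EI (default sd 0.005, roughly
1% of a typical `EI_max`). No instrument noise model is published; this is
the simplest testable choice and the level is configurable. Curves start at
`start_osm` = 50 mOsm/kg rather than 0: the sweep nominally covers 0–500,
but below complete lysis the diffraction signal is uninformative, so no
samples are emitted there.

Preset parameter sets encode five phenotypes — whole blood (WB),
mock-Percoll-treated whole blood (WBP), and low/medium/high-density
fractions (L/M/H, enriched in young, mature and senescent cells). Absolute
index levels are implementer-chosen plausible constants; what the presets
are *constrained* by is the reported ordering structure: `O_hyper`
decreasing L > M > H with `O_min` equal across fractions; the H-fraction
with the smallest `Area` and `EI_max` but the largest `EI_min`; both L and H
peaking below the M optimum; and WBP right-shifted in `O_min` and `O_hyper`
relative to WB with unchanged `EI_max` (the centrifugation/Percoll swelling
artifact, default +10 mOsm/kg). All tests compare extraction against
generator truth, never against the preset constants themselves.

## Index extraction

`extract_indices()` orchestrates four steps on a raw curve; degenerate
shapes are reported through QC flags (`NO_VALLEY`, `HYPER_NOT_REACHED`,
`LOW_SIGNAL`, `DUPLICATE_OSM`), never as errors — only an input with fewer
than 20 points is fatal (`TOO_FEW_POINTS`).

1. **Preprocess**: sort by osmolality, average EI over duplicate
   osmolalities, drop points outside [0, 500], smooth with a centered
   moving average (default width 5; width 1 disables). A robust noise-scale
   estimate (`median |second difference| / (0.6745 sqrt(6))`) is recorded;
   it is effectively zero for smooth noiseless traces.
2. **Peak**: `EI_max` is the global maximum of the smoothed EI.
3. **Valley**: global minimum restricted to `[search_lo, O_EI_max]`
   (default `search_lo` = 100 mOsm/kg, excluding the sub-lysis bump); the
   minimum must be interior to the window, otherwise `NO_VALLEY`.
4. **Half-max crossing**: `O_hyper` is the *first* downward crossing of
   `EI_max / 2` after the peak, linearly interpolated between the
   bracketing samples. The first rather than the last crossing is used
   because late-arm noise ripples can generate spurious re-crossings.
5. **Area**: trapezoidal integral over `[O_min, O_hyper]` with interpolated
   endpoint values.

**Locating the extrema.** Exact plateaus (tied EI values, e.g. a flat-top
peak) resolve to the mean osmolality of the plateau run — symmetric and
deterministic. For *curved* extrema the obvious alternative, the midpoint of
the band of points within a tolerance of the extremum, is systematically
biased toward the flatter arm: the band extends `sqrt(tol / c)` to each side,
where `c` is the arm curvature, so unequal curvatures shift the midpoint by
up to several mOsm/kg — more than the sub-grid accuracy the generator
round-trip demands. The package therefore refines curved extrema in one of
two ways:

* **Effectively noiseless traces** (noise estimate below the plateau
  tolerance): the zero crossing of the centered finite-difference
  derivative, interpolated between the bracketing samples. Its error is
  bounded by half a grid step regardless of curvature asymmetry.
* **Noisy traces**: the vertex of a quadratic fitted to all points within
  `max(plateau_tol, 8 * sigma_hat / sqrt(window))` of the extremum. The
  widened band averages over the noise instead of chasing the noisy argmax,
  cutting the peak-location standard deviation from ~4–5 mOsm/kg (argmax)
  to ~2 at noise sd 0.005.

Smoothing itself shifts the peak of an asymmetric shape by up to ~1 mOsm/kg;
for that reason the validation of noiseless synthetic curves extracts with
`smooth_window = 1` (smoothing exists to suppress instrument noise and has
no role on noise-free traces). With that configuration, round-trip recovery
over preset-anchored random parameters is within 0.6 mOsm/kg for the three
osmolality indices, 1e-4 for the EI indices, and 0.1% for `Area`.

Two conventions are documented rather than claimed identical to the
instrument vendor's proprietary definitions: the `Area` bounds
`[O_min, O_hyper]` (which make `Area` well-defined exactly when both anchors
exist), and `O_min` as the geometric valley of the curve (the assay
tradition identifies this point with 50% lysis; only curve data exists
here). Preprocessing marks curves it has handled, so extraction is
idempotent: re-extracting a preprocessed curve with the same configuration
gives identical results.

## The cohort generator

`simulate_cohort()` draws donors with the statistical structure a healthy
reference study reports:

* **Composition**: counts, gender-specific uniform age ranges, and
  hemoglobin/hematocrit normals per gender plus shared MCV/MCHC/RDW
  normals, calibrated to the reference table (28 women 18–61 y, Hb
  136.6 ± 7.67 g/L, Hct 41.4 ± 2.69%; 17 men 23–51 y, Hb 151.5 ± 8.92 g/L,
  Hct 46.2 ± 3.07%; shared MCV 89.6 ± 2.58 fL, MCHC 334 ± 11.9 g/L, RDW
  13.2 ± 0.51%). Only ranges and mean ± sd are published, hence uniform
  ages and normal indices.
* **Water fraction**: latent, mean 0.65, coupled negatively to MCHC
  (−8e-4 per g/L) — denser cells carry less water.
* **O_hyper**: `intercept + beta_age * age + beta_water * (water - 0.65) +
  eps`, `eps ~ N(0, sigma_ohyper^2)`, with RDW sharing correlation
  `rho_rdw` (default 0.5) with the standardized residual, so the
  O_hyper–RDW association is positive. Published reports give the age
  effect as a trend rather than a signed coefficient; the default
  `beta_age = +0.3` mOsm/kg/year encodes the upward trend, consistent with
  the positive RDW coupling, and is configurable. With
  `sigma_ohyper = 8` mOsm/kg this makes a 45-donor cohort show the age
  association at roughly the reported strength (p ≈ 0.005); both constants
  were fixed at design time from that consideration, not tuned against
  tests.
* **Remaining indices**: normal around the WB preset with donor-level sds.
* **QC**: hypochromic-RBC percentages uniform on [0, 4.9]% — the replica
  cohort emulates a study population that already passed the < 5%
  iron-deficiency screen.

`simulate_fractions()` emits WB/WBP/L/M/H samples per donor: WBP adds the
Percoll shift to `O_min` and `O_hyper` only; L/M/H add preset-derived offsets
plus per-fraction measurement noise. The per-fraction `O_min` noise is kept
small (sd 0.5 mOsm/kg): the density fractions share the same lysis point, so
residual variation is pipetting-level. The marker panel (band 4.1a:b ratio,
reticulocyte and CD71 percentages, EMA, forward/side scatter, mBBr,
ThiolTracker, DHR, DAF geometric means) is log-normal around
fraction-specific geometric means — fluorescence is positive and
right-skewed, and cytometry software reports geometric means — with a
donor-level log-sd of 0.15 shared across fractions (it cancels in paired
contrasts) and a within-donor log-sd of 0.02. Units are arbitrary; no claim
is made that they match any cytometer. Offset and geometric-mean magnitudes
are implementer-chosen; only the ten ordering relations are constrained.

One ordering required a judgment call: published descriptions of EMA
staining across density fractions are contradictory (both the strongest and
the weakest EMA signal have been asserted for the densest cells). The
generator follows the membrane-surface-loss interpretation — EMA decreasing
from L to H, as band 3 is shed with membrane during senescence; the
direction is encoded in one geometric-mean row and is trivially
reconfigurable.

## Statistical pipeline

The testing procedure mirrors common clinical-laboratory practice:

* **Gate**: Shapiro–Wilk on the *paired differences* (they, not the raw
  samples, are what the t-test assumes normal), at alpha = 0.05 (the gate
  level is our choice; only the gate itself is prescribed). p >= alpha
  selects the paired t-test, otherwise the Wilcoxon signed-rank test.
  Constant differences make the gate undecidable: all-zero differences
  return p = 1 with estimate 0; constant nonzero differences report the
  exact shift with a sign-test p-value (or p = 0 if the t-test is forced).
* **Estimates**: mean difference (t) or Hodges–Lehmann median difference
  (signed-rank), both oriented as `x - y`.
* **Models**: ordinary least squares `index ~ age + gender` (main effects
  only — no interaction structure is published), gender as a two-level
  factor; per-coefficient t-tests and the overall ANOVA F.
* **Multiplicity**: no correction by default (matching the source
  analysis); `run_config(p_adjust = "holm")` adds Holm-adjusted p-values to
  the fraction comparisons.
* **Reference intervals**: per-stratum percentile intervals (default
  2.5–97.5%) using the linear-interpolation quantile rule
  `h = (n - 1) q + 1` (R type 7), pinned explicitly so results are
  bit-reproducible across implementations; strata below `min_n` get
  undefined bounds and a `LOW_N` flag. In the pilot-scale pipeline the
  default `min_n` is 5 because a 45-donor cohort split by age decade cannot
  reach classical reference-interval sample sizes; the standalone
  `reference_interval()` defaults to the conventional 20.

## Morphometry

`measure_cells()` reduces an integer-labeled mask to per-cell measurements:
projected area (pixel count x `pixel_size^2`), centroid, and the
moment-equivalent ellipse axes (axis = 4 sqrt(eigenvalue) of the second
central moment matrix, with the 1/12 per-pixel variance term). "Sphericity"
is defined as minor/major axis of that ellipse — the published description
("longest to shortest diameter ratio closer to 1") is verbal only; the
moment definition was chosen over Feret diameters for noise robustness.
Components under `min_area_px` (default 50 px) are dropped, and
border-touching cells are flagged and excluded from aggregates because
truncated outlines bias area histograms (binwidth 500, left-closed bins, in
the plotted area units). Segmentation itself is out of scope — masks come
from an external segmenter.

`synth_mask()` packs rotated ellipses with sampled areas and axis ratios by
rejection sampling (guard band of one pixel, attempt cap with a packing
error suggesting a larger image) and returns exact per-cell truth, giving
morphometry the same oracle structure as the curve model.

## Marker computations

Water fraction is `1 - dry/wet` from pellet weights. The band 4.1a:b ratio
integrates each band trapezoidally after subtracting a linear baseline
anchored at the minimum intensities just outside each window; band windows
are user-supplied because migration positions depend on the gel, which is
not modeled. This is a documented re-definition of what gel-densitometry
software computes and is expected to agree only qualitatively. Geometric
means are `exp(mean(log(x)))` on strictly positive values.

## Reproducibility and problem sizes

Every random draw flows from one global seed through named substreams
(cohort, curves, per-donor streams), so any stage can be re-run in
isolation from the manifest's recorded seeds; seeded runs are bit-for-bit
reproducible, and seeded helpers restore the caller's RNG state. The
validation suite uses desk-scale sizes chosen to give stable Monte-Carlo
estimates: 100 random curves for the noiseless round trip, 200 noisy
replicates for `O_hyper` robustness, 2000 replicates for the type-I error
of the gated procedure, 200 cohorts of n = 1000 for slope bias and CI
coverage, 500 replica cohorts for the calibration grand means, and 100
donors for the fraction-ordering and marker checks.

## What the synthetic data do and do not show

The generators reproduce the *structure* reported for healthy donors —
calibrated hematology moments, an age effect on `O_hyper` with RDW and
water-content coupling, fraction offsets and marker orderings — but not the
raw-data idiosyncrasies of a real cohort: instrument drift, batch effects,
non-Gaussian index tails, correlated multi-index noise, or the mixed
composition of the L-fraction (which in reality contains both the youngest
cells and terminally senescent density-reversed ones). Passing tests
demonstrate that the extraction and statistical machinery recover what the
generator put in at realistic noise levels; they do not validate the
biological effect sizes themselves, which would require the original
instrument data. Headline inferential results (e.g. the exact p-value of
the age association in a 45-donor cohort) are sampling-dependent and are
therefore *not* acceptance-tested; what is tested is calibration — unbiased
slope recovery, nominal CI coverage and type-I error.

## Known limitations

* The extraction conventions (Area bounds, smoothing, plateau handling)
  are documented choices, not the instrument vendor's proprietary ones;
  absolute index values from real Lorrca exports may differ systematically.
* The curve model has exactly one valley and one peak; pathological
  osmoscans (e.g. severe hereditary spherocytosis with bimodal shapes) are
  outside the generator's family, although the extractor will flag rather
  than crash on them.
* Marker units and magnitudes are arbitrary; only orderings are
  meaningful.
* `O_min` is a curve feature here, not a lysis measurement; fragility
  assays are not modeled.
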
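---
title: "Methods: phantom, signal models, composition model and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom, signal models, composition model and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartiqmap)
```

## Scope and design

`cartiqmap` compares pixel-wise quantitative MRI parameter maps of
articular cartilage cross-sections with a depth-dependent model of tissue
composition. Real osteochondral MRI data for this comparison are not
publicly deposited, so the package is organized around a synthetic
phantom whose ground truth is known exactly: every stage of the pipeline
(geometry, signal simulation, fitting, segmentation, modelling,
statistics) is verifiable end to end. The phantom is first-class, tested
code, not a throwaway fixture.

## The synthetic osteochondral phantom

**Geometry.** The articular surface is a convex circular arc with
configurable curvature, default 4.4/m — the scale of the mean curvature
of a femoral condyle; the osteochondral junction is that arc offset
vertically by the cartilage thickness. Defaults: 15 mm width (a typical
1.5 cm sample block), 2.5 mm thickness (mid-range of the 2–3 mm typical
of condylar cartilage), 0.1 mm isotropic pixels. At 4.4/m the sagitta
across 15 mm is ≈ 0.12 mm, so the vertical thickness offset differs from
a true normal offset by far less than a pixel; a circular arc is
therefore an adequate surface model at this curvature. A flat slab
(curvature 0) is available for analytic checks.

**Ground-truth maps.** Each relaxation time is a strictly increasing
affine function of the local fluid fraction, scaled so the composition
model's full fluid-fraction range spans a physiologic band: T1 550–750 ms,
T1ρ 40–90 ms, T2\* 15–40 ms. These links are deliberately synthetic test
scaffolding — which monotone law actually relates composition to
relaxation in tissue is precisely the open scientific question, and
nothing downstream assumes the links' functional form (the correlation
analysis is rank-based). What the links guarantee is the qualitative sign
structure: relaxation times rise with fluid fraction and fall with
collagen/proteoglycan content and depth.

**Signal simulation.** Noiseless signals follow the three fitted models
exactly (see below), evaluated per pixel per acquisition point. Noise is
Rician on the magnitude signal, `sqrt((S + n1)^2 + n2^2)` with
`n ~ N(0, σ)` and σ = A_max/SNR, because magnitude reconstruction of
complex MRI data produces Rician, not Gaussian, noise — Gaussian noise
would understate the noise-floor bias at low signal. Default SNR is 50 at
peak amplitude; `Inf` disables noise exactly. Background pixels carry
pure noise. Every stochastic stream is derived deterministically from one
root seed and the sequence kind, so runs are byte-reproducible.

**What the phantom does not emulate:** susceptibility and B0
inhomogeneity artifacts, partial-volume mixing at interfaces, bone/marrow
signal, 3-D volume effects, and any true biological
composition–relaxation law. A green end-to-end test therefore establishes
that the pipeline is self-consistent and recovers known truth under
realistic noise — not that the biological correlations would have the
observed magnitudes in tissue.

## Signal models and fitting

Fitted per pixel, in a least-squares sense:

- T2\*: `S = A exp(-TE/T2*) [+ B]`
- T1ρ: `S = A exp(-TSL/T1ρ) [+ B]`
- T1: `S = |A (1 - 2 exp(-TI/T1) + exp(-TR/T1))|`

Default timings: inversion times 150–1500 ms at TR 3000 ms; spin-lock
durations 0–40 ms; echo times 3.9 + n·6.9 ms (n = 0..14), of which only
TE < 60 ms enter the T2\* fit (9 echoes) — long echoes are noise-floor
dominated.

**Noise floor B.** The mono-exponential models accept an optional
additive floor, default off: with only 5 spin-lock durations a 3-parameter
fit is poorly identified, and the 60 ms echo cutoff removes the
floor-dominated T2\* points. The flag exists because the floor is part of
the magnitude-signal physics; both behaviors are tested.

**Optimizer.** Rather than a generic Levenberg–Marquardt on all
parameters, the fits use variable projection: for a fixed time constant
the amplitude (and floor) are linear and solved in closed form, leaving a
1-D profiled sum of squares in the time constant. That profile is
evaluated on a log-spaced grid (60 points; 80 for inversion recovery) and
every local minimum is refined by Brent search in its bracketing
interval. This is the simplest approach that is robust on the
magnitude-IR objective, which is folded (non-smooth) at the null point —
a single-start gradient method can converge to the wrong side of the
fold. The time constant is capped at 10× the longest acquisition time;
hitting the cap, a constant signal, or a non-finite solution is reported
as `converged = FALSE`, never silently imputed.

**Quality control.** Fit quality is the adjusted R²,
`1 - (1 - R²)(n - 1)/(n - p - 1)`; pixels below 0.95 (or unconverged) are
flagged and excluded from downstream statistics. The threshold is applied
to the *adjusted* statistic throughout, since that is the variant the QC
rule is defined with. Noiseless closure recovers all three maps to
< 0.1 % with 100 % QC pass; at SNR 50 the median time-constant error is
below 5 % and the bias below 2 % (seeded simulations in the test suite).

## Depth, zones, regions

Per-pixel normalized depth is `z = d_surf / (d_surf + d_bone)` from exact
point-to-polyline Euclidean distances to the two boundary curves. The
choice is a package decision: per-pixel depth on curved samples has no
unique definition, and this one is rotation invariant, reduces to the
linear coordinate on flat slabs (column-wise R² = 1 against row index),
and matches the "normalized sample depth" abscissa convention of
depth-profile plots. A column-wise alternative is available via
`method = "column"` for flat-slab work.

Zones use half-open intervals SZ [0, 0.15), TZ [0.15, 0.65),
DZ [0.65, 1]: the conventional percent labels ("0–15 %", "15–65 %")
overlap at the boundaries, so a tie rule is required — ties go to the
deeper zone. The central region is the 6 mm band of columns centered on
the mask centroid column (the anchor is unspecified in the source
convention; the centroid is the natural choice for convex samples);
the peripheral region is the remainder. An optional rectangular-element
grid (`discretize()`) pools pixels to elements by mean depth, mirroring
element-wise model discretization; per-pixel evaluation is the default
for the statistics.

## The composition model

Volume fractions of fluid, collagen and proteoglycan satisfy
`φ_fluid + φ_CO + φ_PG = 1` at every depth, with solid fraction
`φ_s = 1 − φ_fluid`. The published depth profiles exist only graphically;
the only printed numbers are the zonal means (FF 78/70/51 %, CO 8/9/20 %,
PG 14/20/29 %). The default model is therefore *calibrated*: continuous
monotone piecewise-linear FF and CO profiles with knots at z = 0, 0.15,
0.65, 1, whose uniform-depth zonal means reproduce those targets, with PG
as the conservation remainder — so the sum constraint holds at machine
precision by construction. Piecewise-linear (rather than higher-order)
segments are the package's choice: with three zonal-mean constraints per
constituent and a surface anchor they are exactly determined, monotone by
inspection, and nothing in the downstream rank statistics can distinguish
the interpolant family.

Two numerical points. First, the transitional-zone row of the published
means sums to 99 % — rounding in the source — which conservation cannot
reproduce; the calibration closes each zone's sum to 100 % by spreading
the residual evenly (TZ becomes 70.33/9.33/20.33, every cell within
0.34 points of its printed value). Second, the surface anchors
(FF 0.82, CO 0.075) are chosen once as physiologically sensible surface
values consistent with monotonicity; zonal means are insensitive to them
by construction of the calibration.

The fiber model is the Benninghoff arcade: mean fiber angle 90° from the
local surface normal in the superficial zone, 0° in the deep zone, linear
across the transitional zone (continuous, Lipschitz with constant 180).
Eight fiber families are constructed equiangularly about the mean
direction (symmetric fan, so the circular mean equals the mean angle);
they are exported for model fidelity but do not enter the correlation
analysis, which uses only the mean angle. The published transitional-zone
angle SD (32°) exceeds the 26° of an ideal uniform ramp — plausibly a
pixel-weighting effect on curved samples — so SDs are reported but never
asserted against.

## Statistics

**Spearman ρ_s** is computed as the Pearson correlation of midranks
(tie-corrected), authored in the package and cross-checked in the tests
against an independent brute-force midrank oracle at 10⁻¹² on a thousand
random tied vectors. Two-sided p-values: exact permutation enumeration
for n ≤ 7, otherwise the t approximation `t = ρ√((n−2)/(1−ρ²))` — at the
pixel counts of the correlation table (hundreds to thousands) the
approximation is exact for practical purposes. Correlations are computed
per pixel (not per element), per region, on QC-passing pixels, for all
3 × 4 parameter pairs × 2 regions = 24 results; pixels are pooled across
the sample, and rank-based invariance under monotone transforms of either
map is property-tested.

**Trend fits.** Fraction–qMRI scatters are fitted with `a·exp(b·φ) + c`
and angle–qMRI scatters with `a·sin(b·θ) + c` (θ in radians internally),
by the same profiled-linear strategy as the signal fits, with multi-start
over the sign and magnitude of `b` (the sinusoidal profile is multimodal
in the frequency). "Best fit" is implemented as SSE minimization, i.e.
R² maximization; a constant response is flagged degenerate rather than
fitted. Because the intercept is free, the fitted R² can never fall below
the best constant model's.

**Group comparisons.** Two groups (regions): Mann–Whitney U. Three
groups (zones): Kruskal–Wallis, followed — only when the omnibus test is
significant at 0.05 — by Dunn's post hoc test on pooled tie-corrected
ranks. Dunn's test is implemented in the package (no suitable installed
implementation) with Bonferroni adjustment across the three pairwise
comparisons by default; Holm or no adjustment are available by flag,
since naming Dunn's test does not by itself fix an adjustment. All tests
are two-sided.

## Pipeline and reproducibility

`run_pipeline()` executes phantom → geometry → relaxometry → tissue model
→ statistics from a single `run_config()`; every constant (zone
boundaries, 6 mm CR width, QC 0.95, 60 ms TE cutoff, protocol timings,
curvature) is a named, defaulted key. Errors carry stage tags; QC
failures and empty cells warn but never abort. All artifacts are
plain-text (CSV matrices and tables, YAML config/protocols, JSON report)
— no NIfTI writer is available in this R environment, so rasters travel
as headerless CSV behind the same read/write surface — and a run is
byte-identical given config + seed. The package's interface is the
functions plus the thin `inst/scripts/run_pipeline.R` wrapper; it is an
analysis library, not a shell tool.

## Known limitations

- The composition→relaxation links are synthetic; magnitudes of
  end-to-end correlations on the phantom say nothing about tissue.
- 2-D single-slice geometry only; no artifact physics.
- The default T1ρ protocol has 5 points: with noise, a non-trivial
  fraction of pixels legitimately fails the 0.95 QC gate (≈ 7 % at
  SNR 50), and the optional noise-floor fit is discouraged there.
- Depth on strongly concave or irregular masks is untested; the distance
  definition remains well-posed but zone geometry may not be meaningful.
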
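# cartiqmap

Quantitative MRI (qMRI) relaxometry of articular cartilage, compared
pixel-by-pixel against a depth-dependent computational model of tissue
composition.

## The problem

Cartilage degenerates from the inside out: water content, collagen and
proteoglycan concentrations, and the collagen fiber architecture all change
with depth and with disease, long before morphological imaging shows
anything. Quantitative MRI maps — T1 (inversion recovery), T1ρ (spin lock)
and T2\* (multi-gradient echo) — are candidate biomarkers for these
compositional properties, but each parameter's specificity is disputed.
One way to probe it is to correlate measured parameter maps of
osteochondral samples with an idealized, depth-dependent model of what the
tissue is made of.

`cartiqmap` implements that comparison as a reproducible pipeline for
people working on cartilage qMRI validation: signal-model fitting,
depth-normalized segmentation, the composition/fiber model, and the
statistics — plus a synthetic osteochondral phantom with known ground
truth, so every stage can be verified without scanner data.

## The model in brief

**Signal models** (magnitude MRI, fitted per pixel by least squares):

- T2\*: S(T_E) = A·exp(−T_E/T2\*), echo times < 60 ms only
- T1ρ: S(T_SL) = A·exp(−T_SL/T1ρ)
- T1: S(T_I) = |A·(1 − 2·exp(−T_I/T1) + exp(−T_R/T1))|

with amplitude A and optional noise floor B; fit quality is gated at
adjusted R² ≥ 0.95.

**Tissue model**: at normalized depth z ∈ [0, 1] (0 = articular surface,
1 = osteochondral junction) the fluid, collagen and proteoglycan volume
fractions satisfy φ_fluid + φ_CO + φ_PG = 1 with φ_s = 1 − φ_fluid; the
default profiles are monotone piecewise-linear curves calibrated so that
uniform-depth zonal means reproduce FF 78/70/51 %, CO 8/9/20 % and
PG 14/20/29 % in the superficial (0–15 %), transitional (15–65 %) and
deep (65–100 %) zones. The mean collagen fiber orientation follows the
Benninghoff arcade: 90° from the surface normal in the superficial zone,
0° in the deep zone, linear in between, with eight equiangular fiber
families about the mean direction.

**Statistics**: pixel-wise Spearman ρ_s of each qMRI map against each
modelled parameter (FF, CO, PG, CFO), separately for a 6 mm central region
(CR) and the peripheral remainder (PR); exponential (fractions) and
sinusoidal (fiber angle) trend fits; Mann–Whitney U across regions and
Kruskal–Wallis with Dunn's post hoc across zones.

## Worked example

```r
library(cartiqmap)
rep <- run_pipeline(run_config(seed = 1))
print(rep)
#> <run_report> seed 1
#>   phantom: 3750 masked pixels
#>   QC pass rates: T1 100.0%, T1RHO 92.6%, T2STAR 100.0%
#>   correlation table: 24 rows
```

The default run builds a 15 mm × 2.5 mm phantom with the 4.4/m condylar
surface curvature at 0.1 mm pixels, simulates the three acquisitions at
SNR 50 under Rician noise, fits 3750 pixels per sequence and correlates
the fitted maps with the modelled composition. The noisy 5-point T1ρ fit
is the hardest, hence its ~93 % QC pass rate. The correlation table
carries the expected sign structure — relaxation times increase with fluid
fraction and fiber angle, decrease with collagen and proteoglycan:

```r
subset(rep$correlation, region == "CR" & qmri == "T1")
#>   qmri model_param region      rho_s p_value n_pixels stars
#> 1   T1          FF     CR  0.9333085       0     1500   ***
#> 2   T1          CO     CR -0.9333090       0     1500   ***
#> 3   T1          PG     CR -0.9333078       0     1500   ***
#> 4   T1         CFO     CR  0.9045578       0     1500   ***
```

and the zonal T1 summary shows the decline towards the deep zone that the
model's falling fluid fraction imposes through the phantom's links
(mean ± SD, ms):

```r
rep$zonal_qmri$T1
#>   zone region    n  mean    sd
#> 1   SZ     CR  180 733.1 17.91
#> 3   TZ     CR  780 697.8 14.25
#> 5   DZ     CR  540 612.4 40.43
```

The analytic zonal means of the calibrated composition model itself:

```r
model_zonal_means()
#>   zone    ff     co    pg cfo
#> SZ   SZ 78.00  8.000 14.00  90
#> TZ   TZ 70.33  9.333 20.33  45
#> DZ   DZ 51.00 20.000 29.00   0
```

(The transitional-zone targets absorb a 1/3-point closure correction: the
published 70/9/20 row sums to 99 %, which volume-fraction conservation
cannot reproduce exactly.)

A YAML-driven command-line entry point is provided at
`inst/scripts/run_pipeline.R`; all artifacts (maps, label tables, summary
and correlation tables, curve fits, report) are written as plain-text
CSV/YAML/JSON and runs are byte-reproducible from config + seed.

## Acceptance script

`scripts/acceptance.R` recomputes, from the installed package, the
uniform-depth zonal means of the calibrated composition model (fluid,
collagen and proteoglycan fractions in percent) and of the fiber-angle
ramp (degrees), and the minimum adjusted R² of a pixel-wise
mono-exponential fit on a noise-free T2\* stack with the standard echo
series after the sub-60 ms filter. Run it from the repository root:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
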
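# miiquant

Rapid quantification of filamentous-fungal biomass in submerged culture from
bright-field micrographs.

Dry cell weight (DCW) is the reference biomass measure for fungi such as
*Cordyceps militaris* that grow as spores, dispersed branching hyphae and
pellets, but it requires centrifugation, filtration and one to two days of
drying — far too slow for monitoring a running fermentation. `miiquant`
implements the *microscopic image intensity* (MII) approach instead: a
micrograph of the culture is transformed so that only mycelium pixels
remain, the frame is summarised by its mean gray level (the MII statistic),
and a simple linear calibration converts intensity to biomass within
seconds of image capture.

## The method

**Image transformation.** Each 24-bit micrograph is converted to 8-bit
grayscale and passed through an ImageJ-style operator chain:

1. primary gray-level threshold at 154 (mycelium is darker than the medium),
   giving a provisional colony mask;
2. rolling-ball background subtraction (grayscale closing with a disc,
   default radius 50 px), which removes the uneven bright field and leaves
   the mycelium signal bright on dark;
3. linear contrast enhancement (0.35 % saturated tails);
4. secondary threshold at 180 on the enhanced image, gated by the dilated
   provisional mask;
5. median filtering (radius 1) and removal of connected components smaller
   than 20 px (specks that cannot be mycelium);
6. all non-mycelium pixels are zeroed and the MII is the mean gray level of
   the resulting frame.

Every stage and its parameters are configurable through `mii_config()` and
recorded in the result's provenance.

**Calibration.** MII (x) is related to DCW (y, mg/L) by ordinary least
squares:

    y = β₀ + β₁ x + ε

`fit_mii_calibration()` returns the full verification panel — coefficients
with standard errors, the standardized coefficient (= Pearson r), t and F
statistics with p-values, R², and 95 % confidence intervals — with
`tidy()`, `glance()`, `autoplot()` and `verification_table()` accessors.
Predictions are scored against measured DCW with the symmetric degree of
accuracy `100 · min(ŷ, y) / max(ŷ, y)`, and `dilution_analysis()` reports
per-dilution-factor calibration quality (R² degrades as samples are diluted
and fewer objects fall in the frame).

**Synthetic micrographs.** Because micrograph archives of this kind are
rarely deposited, the package ships a seeded generator
(`scene_spec()`/`generate_scene()`) that renders dark branching hyphae
(correlated random walks), spores (ellipses) and pellets (dense disks) on a
bright, unevenly illuminated background with Gaussian noise and impulse
specks — with per-pixel ground truth, so every pipeline stage is testable
end to end.

## Worked example

```r
library(miiquant)

# a synthetic micrograph with known ground truth
scene  <- generate_scene(scene_spec(n_hyphae = 15, seed = 7))
result <- transform_image(scene$image, mii_config())
result
#> <mii_transform> 128x128 px | MII = 22.342 | mask area = 2021 px (12.34%)

# calibrate MII against DCW on synthetic samples drawn from the model line
d   <- simulate_calibration(n = 30, seed = 1)
fit <- fit_mii_calibration(d)
verification_table(fit)
#> Model verification (simple linear regression)
#> Variable                B   Std. error         Beta            t
#> (Constant)         72.784       10.450            -     6.965***
#> MII                 5.960        0.219        0.982    27.227***
#> F = 741.335*** | R^2 = 0.964
#> *p < 0.05, **p < 0.01, ***p < 0.001

# predict biomass for a new sample and score it against the measured DCW
predict_dcw(fit, tibble::tibble(sample_id = "A", mii = 23.9, dcw = 240.5))
#> # A tibble: 1 × 5
#>   sample_id   mii   dcw predicted_dcw accuracy_pct
#> 1 A          23.9  240.          215.         89.5
```

The MII of 22.3 reflects the ~12 % mycelial coverage of the frame; the
fitted intercept (72.8 mg/L) and slope (5.96 mg/L per intensity unit)
recover the generating line within their standard errors; and the predicted
DCW of 215 mg/L agrees with the measured 240 mg/L to 89.5 %.

A command-line interface over the same functions is installed at
`inst/cli/miiquant` with subcommands `transform`, `calibrate`, `predict`,
`dilution`, `simulate` and `simulate-calibration`; each run writes a JSON
manifest (tool version, config hash, inputs/outputs) beside its output.

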
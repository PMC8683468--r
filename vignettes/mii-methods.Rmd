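---
title: "Quantifying mycelial biomass from microscopic image intensity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mycelial biomass from microscopic image intensity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miiquant)
```

## The problem

Filamentous fungi in submerged fermentation grow as a mixture of spores,
dispersed branching hyphae and dense pellets. The reference biomass
measure, dry cell weight (DCW, mg/L), needs centrifugation, washing,
filtration and up to 48 h of drying, so it cannot support same-day process
decisions. Optical-density methods fail because the culture is neither
uniform nor unicellular. The approach implemented here replaces the
gravimetric step with image analysis: a bright-field micrograph is
transformed so that only mycelium pixels carry signal, the frame is reduced
to a single intensity statistic (MII), and a pre-established linear
calibration maps intensity to DCW.

The package has three parts: the image-transformation chain
(`transform_image()`), the calibration statistics
(`fit_mii_calibration()` and friends), and a synthetic-micrograph
generator (`generate_scene()`) that supplies ground-truth test material.

## The transformation chain

`transform_image()` applies, in order: grayscale conversion, a primary
threshold, rolling-ball background subtraction, contrast enhancement, a
gated secondary threshold, median filtering, small-object removal,
background zeroing, and MII measurement. All stages operate on integer
matrices in [0, 255]; every stage and its parameters are appended to the
result's provenance vector.

### Parameters and defaults

| parameter | default | unit | role |
|---|---|---|---|
| `threshold_primary` | 154 | gray level | provisional mycelium/medium cut on the raw grayscale image |
| `threshold_secondary` | 180 | gray level | final cut on the enhanced, background-subtracted image |
| `foreground_polarity` | `dark_on_bright` | — | bright-field convention: mycelium is darker than the medium |
| `background_radius` | 50 | px | disc radius of the rolling-ball background estimate |
| `contrast_saturation` | 0.0035 | fraction | saturated tail mass of the linear stretch |
| `dilation_selem` | `square3` | — | structuring element for dilating the primary mask |
| `median_radius` | 1 | px | median-filter window radius |
| `min_object_area` | 20 | px | smallest connected component kept |
| `maxima_prominence` | 10 | gray levels | annotates which removed components were isolated intensity peaks |
| `mii_mode` | `whole_image` | — | MII as mean over the full zeroed frame |

The two threshold levels are the published workflow's values and are kept
as defaults. The remaining knobs are not stated by that workflow; the
defaults here are the conventional ones for the tooling the workflow was
built on (rolling-ball radius 50 px, 0.35 % contrast saturation, 3×3
dilation, radius-1 median), and all are exposed in `mii_config()`.

### Design decisions in the chain

Several aspects of the published workflow are underdetermined, and the
package fixes them as follows.

**Threshold polarity.** Whether a threshold selects above or below its
level is never stated. In bright-field images mycelium is darker than the
medium, so the primary threshold keeps pixels `<= 154`. Background
subtraction returns `background − image`, which inverts the signal, so the
secondary threshold keeps pixels `>= 180`. Both polarities are
configurable. A pixel exactly at the level is always foreground.

**How the two thresholds combine.** The chain lists both thresholds
without saying how their masks interact. Here the secondary (180) mask is
ANDed with the *dilated* primary (154) mask: the primary mask marks where
the colony plausibly is, its dilation tolerates one-pixel misregistration,
and the gate prevents contrast-enhancement artifacts in pure-background
regions (where the stretch amplifies noise to full range) from entering
the final mask. This matches the narrative order of the stages.

**Rolling ball as flat-disc morphology.** The background of a
dark-on-bright image is estimated by grayscale closing with a flat disc
(pixels at squared distance `<= r²` from the centre), the standard
flat-structuring-element form of the rolling-ball filter. Closing of the
*image* equals opening of the *inverted* image, inverted back; tests
exploit this identity against a brute-force oracle. Near the frame border
the closing of a steep illumination ramp is inflated within one radius of
the edge — an inherent property of border-truncated morphology, shared by
the oracle — so background flatness claims hold either for gentle ramps or
away from the border.

**"Find maximum" noise removal.** The original description of the final
clean-up ("median filters and tools to find the maximum") is ambiguous. It
is operationalised as: remove every 8-connected component smaller than
`min_object_area` pixels, and annotate each removal with its intensity
prominence (component extremum minus the median gray level of its
one-pixel surround) so speck-like removals — isolated maxima with
prominence above `maxima_prominence` — are identifiable in the result
metadata. Since any prominent component *below* the area floor is removed
by the area rule already, the area rule subsumes the prominence rule; the
prominence threshold therefore only classifies removals, it does not
change the mask. A component of exactly `min_object_area` pixels is
retained.

**MII definition.** "Intensity" of the transformed image is taken as the
arithmetic mean gray level over the whole background-zeroed frame
(`whole_image`). This makes MII proportional to mycelial coverage times
mean mycelium brightness, so it rises as the culture grows, which is the
behaviour the calibration requires. The alternative `mask_only` mean
(brightness of mycelium pixels only, insensitive to coverage) is provided
for completeness.

### Numerical conventions

Rounding is half-up (`floor(x + 0.5)`) everywhere so masks and transformed
images are bit-identical across platforms. Quantiles in the contrast
stretch use R's default (type 7) definition; a constant image is returned
unchanged. Median windows at the frame border are truncated to in-bounds
pixels. Connected components use 8-connectivity (EBImage's labeller is
4-connected, so labelling is implemented in-package and verified against a
flood-fill oracle). Coordinates are row-major with origin at the top-left.
The whole chain is deterministic: identical input and config give
bit-identical results, which the test suite asserts with `identical()`.

## Calibration statistics

`fit_mii_calibration()` fits `dcw = β₀ + β₁ · mii + ε` by ordinary least
squares (delegated to `stats::lm`; an independent normal-equation oracle
in the test suite checks every reported field to 1e−9 relative). Reported
alongside the coefficients: standard errors from the residual mean square,
two-sided t tests on n − 2 df, the ANOVA F on (1, n − 2) df, R², the
standardized coefficient `β₁ · sd(x)/sd(y)` (equal to Pearson's r, so its
square equals R² and `t² = F` — both identities are tested on every fit),
and 95 % t-based confidence intervals. Calibrations with fewer than three
complete pairs or without intensity spread are refused: a calibration with
no x-variance is meaningless rather than ill-conditioned, so no
pseudo-inverse fallback is offered. p-values are two-sided; no
multiple-testing correction is applied because a single model is tested.

**Degree of accuracy.** Agreement between predicted and measured DCW is
`100 · min(ŷ, y) / max(ŷ, y)` percent. This symmetric min/max form is
adopted because it reproduces both recoverable printed verification pairs
of the source workflow (270.1 vs 240.5 → 89.0 %; 383.9 vs 409.9 → 93.7 %),
which a fixed-denominator relative error does not. It is symmetric in its
arguments and never exceeds 100.

**Units.** DCW is treated as mg/L throughout. The package derives
calibration coefficients from data rather than hard-coding any published
equation, because the published equation and the published predictions are
not mutually consistent (applying the printed coefficients to the printed
intensity 23.9 gives ≈ 213 mg/L, not the printed 270.1 mg/L — an
unresolvable units or coding ambiguity in the source). The package
therefore asserts the printed *accuracy pairs*, never the printed
*equation-to-prediction* mapping.

**Dilution analysis.** `dilution_analysis()` fits a separate regression
per dilution-factor group (factors may share a label, e.g. factors 2 and 5
pooled as "2–5") and reports per-group R². Groups with fewer than three
samples yield `NA` rather than an error, since an undefined fit is a data
property, not a usage error.

## The synthetic generator

`generate_scene()` renders what the pipeline needs to see: dark objects at
`foreground_level` 80 on a background at 200 with a 20-gray-level linear
illumination ramp, Gaussian pixel noise (sd 3) and 30 dark impulse specks
of 1–4 px. Hyphae are correlated random walks (Gaussian turning angle,
sd 0.25 rad) of mean length 40 px and thickness 2 px, branching with
probability 0.08 per step; spores are small ellipses; pellets are dense
disks of radius ~8 px. These morphology parameters are plausible values
chosen here — no quantitative morphology is published for the source
system — and the gray levels are chosen so that mycelium falls below the
154 threshold and background stays above it, which is precisely the regime
the published thresholds imply for real material. Ground truth (mask,
per-object labels, pixel biomass) is recorded before noise, so impulse
specks are non-truth by construction and exercise the median-filter and
small-object-removal stages.

Determinism: every generator phase (spores, hyphae, pellets, noise) runs
under its own seed derived from the spec seed, so adding an object type
does not perturb earlier draws; identical specs give bit-identical scenes.

`generate_growth_series()` emulates culture staging — spores first,
branching hyphae from the second stage, pellets only in the final third —
by *cumulative* construction: each stage adds objects to the previous
truth, so biomass is non-decreasing by construction rather than by luck.
`simulate_density_ramp()` uses the same trick for strictly increasing
density ramps.

`simulate_calibration()` draws MII uniformly on [20, 70] (the intensity
range of the source's working regime) and generates DCW from the line with
intercept 70.095 and slope 5.982 — the published calibration, used here as
simulation truth — plus Gaussian noise, truncated at zero. The default
noise sd of 22 mg/L puts the realised R² near 0.94, the published
calibration quality; with the default intensity spread the truncation at
zero is never active.

**Dilution samples.** `scene_to_dilution_samples()` models the dilution
experiment through counting statistics rather than per-sample pixel
rendering: a sample at concentration `c` diluted `f`-fold presents
`λ = n₀ · (c/c_ref)/f` objects to the frame (defaults: `n₀ = 240` objects
undiluted in a 256×256 frame, `c` uniform on 100–500 mg/L), the realised
count fluctuates by `dispersion · √λ`, and the measured coverage is
converted to intensity and rescaled by `f` to undiluted-equivalent MII.
Fewer objects in the frame at higher dilution thus means larger relative
counting error, so per-group calibration R² decreases with the dilution
factor *by construction* — the mechanism the dilution experiment is
probing — without any per-factor noise knob. Rendering was deliberately
avoided here: the pipeline's MII is a near-deterministic function of
coverage (that link is tested separately by the ramp-monotonicity
property), so rendering hundreds of frames inside the dilution analysis
would add cost without adding information. With `dispersion = 0` the
samples lie exactly on a line.

### What the generator does not emulate

No point-spread function, defocus or halo optics; no 3-D pellet structure
(pellets are flat disks); no anti-aliased object edges (objects are
stamped at a single gray level); no resolution/magnification model — MII
is resolution-dependent and no physical pixel size is assumed. Passing
tests on this material therefore demonstrate that the operator chain and
statistics behave as specified on dark-on-bright filamentous scenes; they
do not certify accuracy on any particular microscope's output, which
always requires recalibration against local DCW measurements.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` use: 100 random 16×16 instances
per elementary-operator oracle; 100 random datasets for the OLS oracle;
500 replicates at n = 30 for slope-CI coverage (expected in 93–97 %);
a 20-scene 128×128 density ramp for MII monotonicity (Spearman ρ ≥ 0.9);
8 scenes for mask F1 against truth (threshold 0.8); and 10 seeds × 40
replicates per factor for the dilution R² ordering (strictly decreasing in
at least 9 of 10). These sizes give stable statistics for the properties
being checked while keeping a full run in the order of a minute.

## Known limitations

- The exact semantics of the original workflow's final clean-up stage
  cannot be recovered from its description; the operationalisation above
  is an interpretation, flagged as such.
- Whether published MII values were measured on whole frames or regions of
  interest is unknown; the package measures whole frames by default.
- MII saturates once mycelium overlaps heavily (coverage no longer
  proportional to biomass), so the linear calibration holds only in the
  dilution regime where objects are resolvable — which is what the
  dilution analysis is for.
- The calibration is strain-, medium-, magnification- and
  illumination-specific; coefficients must be re-estimated for any new
  imaging setup.
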
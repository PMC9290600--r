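---
title: "Models and methods behind cbcsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cbcsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbcsim)
```

`cbcsim` is a desk-scale re-implementation of the measurement and validation
machinery behind microscopy-based complete blood count (CBC) analyzers: a
diluted, fluorescently stained blood aliquot settles into a monolayer inside
a shallow chamber, an automated microscope scans a couple of hundred fields
in five spectral channels, three analysis pipelines turn the micrographs into
red-cell, white-cell and platelet measurements, a reagent-free photometric
chamber provides total hemoglobin, and the instrument reports a 19-parameter,
five-part-differential CBC with abnormality flags. No public dataset of such
micrographs exists, so the package's synthetic sample generator is a
first-class component: every pipeline is exercised and validated against the
generator's per-cell ground truth.

This vignette records the models, the tunable parameters with their units and
defaults, the numerical choices, and the limits of what a green test
establishes.

## The stated world of the generator

`population_params()` defaults are the normal-range pooled means of the
device's whole-blood repeatability study: RBC 5.04 x 10^6/ul, WBC
9.26 x 10^3/ul, PLT 309 x 10^3/ul, HGB 14.81 g/dl, MCV 85.28 fl, RDW 15%
(the red-cell volume distribution is lognormal with CV = RDW), and a
five-part differential of 66.8 / 22.6 / 7.7 / 2.3 / 0.5 percent
(NEUT/LYMPH/MONO/EOS/BASO). Per-cell hemoglobin concentration is normal
around the population MCHC implied by `hgb / (rbc_conc * mcv_mean)`, SD
1.2 g/dl. Abnormal classes (blasts, immature granulocytes, atypical
lymphocytes, nucleated red cells) default to zero and are switched on per
experiment. Debris -- nuclear-only fragments and dim speckles -- is generated
as a distinct kind at 2 x 10^3/ul so that the candidate filters face true
negatives.

Counts are Poisson in concentration times sampled blood-equivalent volume.
The volume imaged by a scan is `n_fields x field_area x chamber_height /
dilution_factor` (`imaged_blood_volume()`), which ties every reported
concentration back to counting statistics.

### Settling: why placement is hard-core, not independent

The physical device settles cells onto the chamber floor, where they exclude
each other; its stated property is that settled cells rarely overlap at any
red-cell concentration up to 8 x 10^6/ul. Independent uniform placement
cannot reproduce that: at a settled density high enough to see hundreds of
white cells per scan, independently placed red-cell footprints would overlap
almost surely. `settle_fields()` therefore uses random sequential placement
with a hard core: each cell draws uniform positions until its footprint
(times a small gap factor, `hard_gap = 1.08`) clears all previously settled
cells, and is force-placed after `max_tries` failures so the sample is
conserved exactly. Large cells settle first. The remaining overlap graph is
reported per field, and the monolayer contract -- fewer than 10% of red cells
in the overlap graph at 8 x 10^6/ul -- is tested against an independent
pairwise-distance oracle.

### Geometry and dilution defaults

The paper-level description fixes the chamber height order ("a few hundred
microns") and the minimum field count (200), but neither the dilution ratio
nor the field size. The package picks, once:

* `chamber_height = 300` um, `n_fields = 200`;
* `field_width = field_height = 500` um at `pixel_size = 1` um/px;
* `dilution_factor = 300`.

These jointly give a settled red-cell coverage of about 33% at the top of the
range (8 x 10^6/ul) -- a dense but feasible hard-core monolayer -- and an
expected 450-500 white-cell candidates per default scan, inside the "order of
a thousand" contract (asserted as 300-3000). They are configuration values,
not claims about the device.

### Optics and rendering

Five channels: violet/green/red brightfield (405/517/633 nm) and UV/blue
fluorescence excitation (365/460 nm). Brightfield channels obey Beer-Lambert:
`I = background * 10^(-eps(lambda) * D)`, where `D` is the hemoglobin
optical path density (g/dl x um) along the footprint and `eps` is greatest in
the violet (0.008 per (g/dl) um; hemoglobin absorbs violet strongly). Red
cells render with the classic biconcave radial thickness profile
`g(u) = sqrt(1-u^2)(0.81 + 7.83u^2 - 4.39u^4)`, normalized so the profile
integrates to the cell volume; footprint radius scales isometrically,
`r = 3.6 um x (V / 90 fl)^(1/3)`.

The UV-excited channel carries the nuclear DNA stain; the blue-excited
channel carries the second stain (DNA/RNA/acidic organelles) and is acquired
at 8x exposure so platelets, dim for their low RNA content, stand above
background. White-cell classes differ by footprint radius, nucleus radius and
lobe count, nuclear aspect ratio, stain responses, and granule painting
(eosinophil-like granules in the blue channel, basophil-like granules in the
UV channel); `wbc_class_table()` holds the whole class model. Nucleated red
cells are nucleated *and* hemoglobin-positive, which is what lets the
classifier separate them via the brightfield-absorption feature.

Camera noise is the standard Gaussian approximation of shot noise, variance
`gain * signal` (gain 0.05), plus additive read noise (SD 2 counts), on every
channel. Rendering uses 2x2 subpixel sampling for anti-aliased footprints.
The generator does *not* model optical point-spread beyond that, fluorophore
spectra, photobleaching, focus errors, or staining variability between
preparations -- so green recovery tests establish correctness of the
measurement inversions under the stated physics, not robustness to real
instrument artifacts.

## Red-cell pipeline

Detection thresholds the violet optical density at
`max(od_k * sigma_od, min_od)`, with `sigma_od` estimated from the image's
own background (median plus one-sided MAD, then a trimmed mean); no fixed
constant is assumed. Connected regions within area bounds are candidates;
regions larger than `split_trigger_area = 72 um^2` are screened for overlaps
and split by a distance-transform watershed seeded at local maxima at least
`split_min_dist = 3.4 um` apart. A split is accepted only when every fragment
passes area and roundness bounds; the fragment union always reproduces the
parent mask exactly.

Per-cell hemoglobin inverts Beer-Lambert: `hb_pg = 0.01 * sum(OD) *
pixel_area / eps(405)` ((g/dl) fl = 0.01 pg). Volume uses the effective
footprint area `A_eff = (sum OD)^2 / sum(OD^2)`, which for a fixed profile is
a shape constant times the true footprint area and is nearly independent of
the detection threshold; `A_eff` is mapped to volume through a calibration
computed on the renderer's own pixel sampling (memoised per pixel size), so
finite-pixel smoothing does not bias MCV. This area-to-volume mapping is the
package's documented stand-in for the device's unpublished absolute volume
measurement: recovery tests check consistency against the simulator's own
profile, not the device's absolute calibration.

Population indices: concentration = all counted masks over the imaged
blood-equivalent volume; MCV/RDW/MCH are computed from interior, unsaturated,
*unsplit* cells only, because clipped border footprints and watershed
fragments carry distorted per-cell values (they still count toward the
concentration). RDW = 100 x SD(volume)/MCV.

## White-cell pipeline

Candidates must show both stains: the cell mask is the union of the
blue-excited excess above `cyt_min` and the UV-excited excess above
`nuc_min`, and a component is kept only with enough nuclear area, total area
within bounds, and non-empty cytoplasm after segmentation (nucleus =
UV-threshold within the cell mask; cytoplasm = cell minus nucleus). This is
what excludes anucleate cells, platelets, dim speckles and nuclear-only
fragments. Candidates rejected at segmentation count as rejects, never as
classes: rejects + classified = candidates.

Features per candidate: cell and nucleus areas, equivalent diameter,
nucleus/cell area ratio, mean and SD of each fluorescence channel over
nucleus and over cytoplasm (the SDs are the texture features), mean violet
brightfield absorption over the cell, nucleus lobedness (perimeter^2 /
4 pi area) and nucleus eccentricity.

The classifier is deliberately classical: linear discriminant analysis by
default (`method = "multinom"` gives an L2-regularised multinomial
alternative), trained on a rendered single-cell gallery
(`render_wbc_gallery()`) that passes through the *same*
detection/segmentation/feature code as field analysis. No tree-ensemble
backend ships in this environment, and the production device's convolutional
networks are out of scope by design; the `method` argument is the
substitution point. On the synthetic class model the five normal classes are
linearly separable and LDA reaches 100% held-out accuracy -- a property of
the stated world, not a claim about real morphology. Ties in the posterior
break by the fixed class order of `wbc_class_table()`.

Nucleated red cells classify as their own class, are excluded from the WBC
concentration, and raise a flag; whether the device reports NRBC per-100-WBC
or only a flag is unstated, so only the flag is implemented.

## Platelet pipeline

Platelet candidates are small connected components of exposure-normalized
blue-excited excess (threshold `excess_k` background SDs), combined with an
absence-of-hemoglobin criterion (mean violet OD below 0.05) that rules out
red-cell fragments. Rule-based filtering accepts per-platelet area 1-15 px^2
(at 1 um/px), peak excess within [4, 30] normalized counts, and roundness
>= 0.4 for single round objects; an optional scoring function can replace
the rules. The peak window is an operating-point choice: the lower bound
keeps the platelet brightness distribution (median peak about 10 counts)
almost fully above threshold while admitting only the extreme tail of the
dim-speckle population (median about 3), and the upper bound excludes the
much brighter cytoplasm fragments of white cells.

Touching platelets merge into one connected component at high
concentrations, so counting is by resolved individuals rather than
components: local maxima of the 3x3-box-smoothed excess (minimum separation
2.2 um) count the members of a group, and components too large or too
elongated to be a single platelet are additionally resolved by local maxima
of the footprint's distance transform -- the same overlap philosophy as the
red-cell splitter. Box smoothing makes a noise-induced second maximum inside
one platelet effectively impossible. Without group resolution the count runs
about 1% low at 800 x 10^3/ul; with it, recovery is unbiased within counting
error across 20-800 x 10^3/ul. Exposure normalization makes the accepted
count invariant to the exposure setting, which is tested noise-free.

## Hemoglobin photometry

The hemoglobin chamber holds undiluted blood read at four wavelengths through
at least two optical path lengths: `A(lambda, L) = eps(lambda) hgb L +
s_coef s(lambda) L + offset(lambda) + noise`. Differential absorbance between
the longest and shortest path cancels every path-independent offset exactly;
the remaining two-parameter model (concentration and a scattering
coefficient on a fixed lambda^-4 spectral basis) is solved by least squares
over the four wavelengths. The actual device wavelengths and inversion are
unpublished; this linear absorption-plus-scattering reading is the minimal
model consistent with "four wavelengths to account for absorption and
scattering", and the defaults (500/570/600/660 nm, paths 50/150 um) are
placeholders chosen so whole-blood absorbances stay measurable. Collinear
absorption/scattering spectra raise an error; a negative solve clips to zero
with a warning.

## Report compilation, flags, validity

The 19 parameters follow the standard identities: HCT = RBC x MCV / 10,
MCH = 10 x HGB / RBC, MCHC = 100 x HGB / HCT; the five-part differential is
taken over the five normal classes so percentages sum to 100 and each
absolute count is WBC x pct/100 by construction, while abnormal classes
count toward WBC (NRBC excluded) and toward their flags. Display rounding is
2 decimals for concentrations and HGB, 1 for percentages and indices;
unrounded values are kept alongside.

Morphological flags require both >= 10 cells and >= 1% of classified white
cells (configurable); the distributional flag fires when any differential
percentage leaves its reference range (defaults NEUT 40-75, LYMPH 20-45,
MONO 2-10, EOS 0-6, BASO 0-2). The validity layer mirrors the instrument's
self-test role at contract level: a run is invalid overall below 100 analyzed
fields or a focus-proxy floor; the differential is invalidated below 50
classified cells; a single class below 10 events invalidates only that
class's percentage and count; low red-cell or platelet event counts
invalidate their measurands. These thresholds are contracts of this package,
not claims about the proprietary production rules.

## Validation statistics

* `passing_bablok()`: slope = shifted median of all pairwise slopes
  (slopes of -1 excluded, shift K = #{S < -1}); intercept =
  median(y - slope x); CIs by the classical rank-based normal approximation
  of the slope order statistics (no bootstrap), intercept bounds reusing the
  slope bounds. The implementation is tested against brute-force enumeration
  on random instances.
* `median_bias()`: median of absolute or relative differences; relative mode
  names any pair with x = 0 in its error. Convention: relative for
  concentrations, absolute for percentages, overridable per analyte.
* `pooled_sd()` / `repeatability_table()`: pooled within-sample SD,
  `sqrt(sum((n_i - 1) s_i^2) / sum(n_i - 1))`; one group reduces to the
  ordinary SD.
* `reproducibility_components()`: balanced nested ANOVA (site > device > day
  > run > replicate) by method of moments on the nested mean squares;
  negative solutions truncate to zero with a note; only the fully balanced
  layout is supported, anything else is an explicit error.
* `clopper_pearson()` / `binomial_agreement()`: exact beta-quantile binomial
  intervals. The study's printed sensitivity/specificity/overall-agreement
  bounds are reproduced exactly by this interval, which is why it was
  adopted; the test suite asserts all six printed bounds.
* `rumke_compare()` / `rumke_arbitrate()`: per-class exact conditional
  two-proportion comparison (hypergeometric conditioning on the combined
  count, i.e. the Fisher construction) between two 200-cell differentials,
  with the third-examiner arbitration protocol (accept any agreeing pair,
  else discard). An exact test was chosen over table lookup; alpha is
  configurable.
* `matrix_comparison()`: replicates averaged per specimen within matrix
  before Passing-Bablok, per analyte, with unpaired specimens excluded and
  logged.

## Numerical and I/O choices

Background levels are estimated per channel from the pixel population
(median, one-sided MAD, trimmed mean within a few sigma), never assumed.
All randomness flows through a single seed; child seeds stay below 2^31.
Identical seeds give bit-identical samples, positions and rasters.

Fields are written as multi-page 32-bit-float TIFF with a JSON sidecar; no
TIFF library ships with this R stack, so the package carries a minimal
little-endian baseline TIFF reader/writer for exactly the subset it emits.
Run configuration is a single declarative JSON file (this environment has no
TOML parser) whose unknown keys are rejected before anything runs. Classifier
artifacts serialize to JSON with a versioned schema header.

## Known limitations

* The area-to-volume mapping is self-calibrated on the simulator's profile;
  absolute MCV accuracy against a real device is out of reach by design.
* Heavy red-cell overlap (beyond occasional pairs and short chains) is
  neither generated at the default dilution nor handled gracefully by the
  watershed acceptance rules.
* The classifier's perfect separability reflects the synthetic class
  geometry; real morphological variation is far harder.
* The headline accuracy tables of the underlying study derive from patient
  samples that are not available; the package reproduces the flagging-study
  arithmetic exactly and validates everything else by property against its
  own generator.
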
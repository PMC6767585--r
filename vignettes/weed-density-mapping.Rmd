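---
title: "Mapping ordinal weed density from multispectral UAS imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping ordinal weed density from multispectral UAS imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weedmapr)
```

## The problem

Black-grass (*Alopecurus myosuroides*) is a grass weed of winter wheat
whose density is scored in the field on a five-level ordinal scale per
20 × 20 m plot: Absent, Low (1–160 plants per 20 m²), Medium (161–450),
High (451–1450) and VeryHigh (1451+). Unmanned aerial systems carrying a
four-band multispectral sensor (green 550 nm, red 660 nm, red-edge
735 nm, NIR 790 nm) can image a whole field in one flight; the analytic
question is whether a convolutional classifier trained on vegetation
index imagery can recover the ground-truthed density state of each plot,
and — critically — whether such models transfer to fields they have
never seen.

`weedmapr` implements that pipeline end to end:

1. **Vegetation index.** GNDVI = (f_n − f_g)/(f_n + f_g) per pixel. The
   green-based index is used rather than NDVI because chlorophyll
   saturation of the red channel in high-biomass wheat flattens the
   red-based index late in the season. NDVI is also provided, in two
   conventions: the package default reproduces the source convention
   (f_r − f_n)/(f_r + f_n), which is the sign-reverse of the textbook
   definition; the `"conventional"` flag selects the latter. Pixels with
   a zero denominator are carried as `NA`, never silently zeroed.
2. **Gridding.** The ground-truth plot grid is overlaid on the index
   raster; each 20 × 20 m plot tile is cut out with half-open pixel
   windows and split into a 4 × 4 grid of 16 subplots indexed from the
   bottom-left (1,1) to the top-right (4,4). Rasters are stored
   top-down while subplot positions count from the bottom-left, the
   single likeliest place for a silent indexing bug; the conversion is
   made in exactly one function each way and is covered by
   marker-pixel and reassembly tests.
3. **Curation.** Class balancing (random downsampling of every state to
   the smallest class count), clean/artefact partitioning of subplots,
   and coverage bracketing of plots by the share of their 16 subplots
   that are clean.
4. **Classification.** A compact CNN over single-channel GNDVI tiles
   with a 5-way softmax head, trained from random initialisation.
5. **Aggregation.** Subplot predictions are upscaled back to the plot
   scale by the median, where the ground truth lives.
6. **Metrics.** One-vs-rest multiclass ROC/AUC, Cohen's kappa, weighted
   kappa, misclassification rate and DeLong AUC comparison.
7. **Experiments.** Baseline 90/10 split, balanced variant,
   clean/artefact cross-prediction, coverage brackets,
   leave-one-field-out cross-validation (LOFO-CV) and temporal grouping.

Because the original survey imagery is not publicly deposited, the
package ships a synthetic-scene generator that reproduces the
*statistical structure* the analysis assumes, so every stage runs and is
tested with no external data.

## The synthetic-scene generator

`field_config()` + `generate_field()`/`generate_survey()` emulate:

* **Plot grid and class imbalance.** 110 plots per ~8 ha field by
  default, density states drawn with the surveyed mixture (Absent
  14.5%, Low 53.1%, Medium 17.3%, High 8.2%, VeryHigh 6.9%).
* **Spatial aggregation.** Plot states come from a latent Gaussian
  random field over the plot grid (white noise smoothed with a Gaussian
  kernel of sd `autocorr_length` plots), rank-transformed to uniform
  and thresholded at the mixture quantiles. Thresholding by within-field
  ranks calibrates the mixture tightly while keeping patchiness; the
  join-count adjacency statistic rises with the autocorrelation length
  (tested by brute force).
* **Pixel model.** Each plot is a two-component mixture: a wheat
  background (GNDVI mean 0.45, sd 0.07) plus clustered weed patches
  thresholded from smoothed within-plot noise. Weed coverage
  (5/15/35/60% of plot pixels by default) and weed GNDVI mean
  (0.62/0.66/0.70/0.74) both rise with state, so the weed signal is
  monotone in density. These defaults are the package's own
  calibration: the empirical per-group GNDVI distributions of the
  original surveys are not published in the main text, so the values
  are chosen to give heavy overlap between wheat and sparse-weed tiles
  (Low coverage means most Low subplots contain no weed pixels at all)
  — which is what makes the realistic profile genuinely hard.
* **Bands from index.** Target GNDVI v and brightness s = f_n + f_g
  determine f_n = s(1+v)/2 and f_g = s(1−v)/2; red is low over
  vegetation and red-edge sits between red and NIR. Gaussian sensor
  noise (sd 0.02 reflectance) is added per band, and bands are clamped
  to [0, 1]. Radiometric calibration, sun angle and stitching artefacts
  are deliberately out of scope.
* **Artefacts.** A Poisson number of objects per field: trees and
  hedgerows as irregular high-NIR canopy blobs (discs and edge
  stripes), tramlines as thin dark stripes crossing the scene. Every
  artefact pixel is recorded in a mask with per-object labels; the mask
  is the oracle that stands in for the original manual screening of
  subplots, which was explicitly manual and non-reproducible. A CSV
  label file can be supplied instead.
* **Seeding.** One master seed; every stochastic stage (each field,
  each split, each training run) derives its own stream from it by a
  fixed hash, so a survey is bit-reproducible at the manifest level.

What the generator does **not** emulate — orthomosaic stitching errors,
variety- and phenology-driven spectral drift, real canopy texture —
bounds what passing tests show: they certify the pipeline's mechanics
and statistical behaviour, not field performance of the classifier on
real imagery.

### Study-condition profiles

`example_config()` freezes three desk-scale conditions (48 plots per
field, 62.5 cm GSD → 32 px plots, 8 px subplots):

* `"realistic"` — the defaults above; subplot-level discrimination is
  hard, as in real surveys.
* `"strong-signal"` — weed coverage (35/55/75/92%) and contrast
  (means 0.60/0.70/0.80/0.90 vs wheat 0.45) raised until states are
  separable by construction, all fields drawn from one shared
  distribution. Used to verify the pipeline recovers a signal it is
  guaranteed to contain.
* `"dataset-shift"` — the strong-signal condition plus per-field
  covariate shift: each field draws an additive GNDVI offset
  (sd 0.15) and a random permutation of the five signal profiles
  (no-weed plus four weed levels) onto its five states. Within any one
  field the states remain separable, but no field-invariant mapping
  from appearance to state exists. An in-sample model retains an
  advantage because a random subplot split leaks sibling subplots of
  every test plot into training; a transferred model misranks.

## The classifier

No deep-learning framework is assumed: the network is implemented in
compiled code inside the package. Both presets share one topology —
3 × 3 convolution + ReLU + 2 × 2 max-pool, twice, then a fully
connected ReLU layer and a 5-way softmax — the four canonical CNN
components. `"small-cnn"` (16 px input, 8/16 filters, 32 hidden units)
trains in seconds on one CPU core; `"googlenet-style"` is a wider
variant of the same blocks, a nod to the large inception-style network
the original analysis trained from scratch, with no attempt at
parameter-for-parameter fidelity. Inputs are single-channel GNDVI tiles
resized by nearest neighbour (index values are preserved exactly;
undefined pixels enter as 0).

Training is momentum SGD (coefficient 0.9) under the step-halving
schedule: the rate starts at `lr0` and halves every `halve_every`
minibatch steps, with categorical cross-entropy and batch size 128.
The constructor defaults (`lr0 = 0.1`, `halve_every = 32000`) are the
survey-scale recipe; the experiment runners default to `lr0 = 0.03`,
5 epochs and `halve_every = 300` because their step budget is two orders of
magnitude smaller and, with raw index-valued inputs, the effective
step lr/(1 − momentum) = 1.0 at rate 0.1 is at the edge of stability —
occasional runs collapse to the class prior, as do some at rate 0.05.
Rate 0.03 is stable in every seeded run we test. All randomness (He-scaled initialisation,
epoch shuffles) is drawn in R from the schedule seed and passed into
the compiled trainer, which is purely deterministic, so training is
exactly reproducible. The backward pass is verified against finite
differences in the test suite.

## Median upscaling and its tie rule

"Median prediction per plot" admits two readings, and both are
implemented: `"median-classes"` (default) takes the lower median of the
contributing subplots' ordinal argmax classes — at even counts the tie
resolves to the lower state, keeping the answer inside the ordinal set
and erring toward lower density; `"median-vectors"` takes the
elementwise median of the score vectors, renormalises and takes the
argmax. Plots whose subplots were all removed by cleaning are emitted
as unpredictable with a zero count rather than dropped, since silently
losing plots would bias the coverage analysis.

## Metric choices

* **Multiclass AUC** is one-vs-rest with an unweighted macro mean over
  scorable classes; per-class curves are the primary output and classes
  with no positives or no negatives are reported unscorable rather than
  dropped. The curve is a threshold sweep whose trapezoidal area equals
  the Mann–Whitney rank probability with ties counted ½ (both
  identities are tested).
* **Weighted kappa** defaults to the banded weight matrix 1, 4, 9, 16,
  25 by ordinal distance |i−j| — the scheme the source analysis states —
  whose diagonal weight is 1, so even perfect agreement scores below 1.
  The conventional quadratic scheme (i−j)² is one flag away, and
  reports carry both. Chance-expected counts use the independence
  model (products of marginals).
* **DeLong's test** backs ROC comparison, in paired and unpaired forms;
  the paired variant is cross-checked against an independent reference
  implementation in the tests.
* **Misclassification rate** is reported in both readings (overall and
  mean per class), since "average across all states" is ambiguous.

## Experiment design notes

The baseline holds out a random stratified 10% of individual subplot
images — deliberately *not* field-blocked, so it is optimistic by
construction; LOFO-CV (one model per field, the held-out field never in
training, metrics at field level over scorable classes only, kappa
deliberately omitted there) is the true out-of-sample test, and the
contrast between the two is the design's point. Temporal grouping fits
two single-predictor OLS regressions of per-field LOFO AUC — year as a
two-level factor, week as numeric 1–6 — and reports adjusted R²;
latitude is confounded with week in the original design and is not
modelled.

## Problem sizes and numerical choices

The experiment suite and tests run at desk scale: 4–20 fields of 48
plots, 8 px subplots, the small-cnn preset, training capped at
6000–8000 tiles per model (a stratified-by-nothing random subsample) —
the whole suite completes in minutes on one CPU. Degenerate inputs are
handled explicitly: zero-denominator index pixels are `NA` and
propagate as masked; single-class test sets are unscorable, not errors;
balancing refuses pools with an absent class, naming it; out-of-bounds
plots are rejected per record, never padded. Scenes travel as plain
multi-band 32-bit TIFF with a JSON sidecar for grid metadata (index
rasters rescaled (v+1)/2 on disk with an explicit definedness band);
models serialise to versioned JSON.

## Worked example

```{r example, eval = FALSE}
library(weedmapr)

survey <- generate_survey(example_config("strong-signal", seed = 11),
                          n_fields = 8)
manifest <- survey_manifest(survey)

baseline <- run_baseline(manifest, seed = 5)
glance(baseline)
autoplot(baseline$metrics$roc)

lofo <- run_lofo(manifest, seed = 5)
mean(lofo$macro_auc, na.rm = TRUE)
run_temporal(lofo)$summary
```

## Known limitations

* The generator's artefact spectra are stylised; real trees, tramlines
  and hedgerows are far more variable, so clean/artefact oracle labels
  are cleaner than manual screening would be.
* The classifier is desk-sized; nothing here estimates how a
  survey-scale network would perform on real orthomosaics.
* Plot grids are axis-aligned in raster coordinates; georeferenced
  rotation and partial boundary plots are out of scope (out-of-extent
  plots are rejected, not padded).
* The red-based index is provided for completeness only; the
  classification pathway is GNDVI throughout.
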
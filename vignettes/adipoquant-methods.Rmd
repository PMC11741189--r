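---
title: "Quantifying adipocyte differentiation from DAPI/BODIPY micrographs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying adipocyte differentiation from DAPI/BODIPY micrographs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipoquant)
```

## Scope

adipoquant quantifies adipogenic differentiation of adherent cultures (for
example iPSC-derived pre-adipocytes) from two-channel confocal fields:
a DAPI channel marking nuclei and a BODIPY channel marking neutral-lipid
droplets. From each field it derives

* the **nucleus count** (total cells),
* a **lipid-droplet segmentation** and per-particle measurements,
* the **differentiation efficiency** — adipocytes / total cells,
* the field-mean **droplet size** (area in µm² and equivalent circular
  diameter in µm), and
* **per-cell lipid content** — the percent of a cell's area covered by
  segmented droplet pixels, averaged over five randomly sampled cells.

A seeded synthetic-field generator with complete ground truth validates
every stage end-to-end; the `delta_delta_ct()` function covers the
companion qPCR readout (fold changes by the 2^−ΔΔCt method).

## The two segmentation pipelines

### Nuclei (DAPI)

1. **Flat background subtraction** of `background_value` (default 50
   intensity units), clipped at zero. The wording of interactive
   workflows ("subtract a *value*") implies a constant offset rather than
   a rolling ball; both primitives exist, and `preprocess_dapi()` follows
   the constant-offset reading.
2. **Gaussian low-pass** with σ = 4 px, reflective boundaries.
3. **Blob detection.** Interactive workflows typically delegate counting
   to a pretrained deep segmentation model; bundling learned weights is
   out of scope here, so detection is classical: a two-scale
   difference-of-Gaussian filter centred on the expected nucleus radius
   (`nucleus_radius_um`, default 5 µm; the blur chain σ/1.6, σ, 1.6 σ with
   the already-applied low-pass deducted, combined by pointwise maximum so
   that small-radius nuclei riding as shoulders on a larger neighbour's
   response are still resolved), regional maxima above an intensity floor
   (by default mean + 8 sd of the Otsu-partitioned background class —
   Otsu's own threshold separates nucleus *interiors* from background and
   would clip dim small nuclei; a fixed floor is available for degenerate
   histograms), and greedy non-maximum suppression at
   `min_separation_um` (default 6 µm, under the typical 8–12 µm murine
   nucleus diameter, suppressing double detections within one nucleus).
   Border-touching nuclei are counted; no sub-pixel refinement is done
   (peak localization on symmetric blobs is already well under the 2 px
   contract).

The accuracy contract, enforced by the test suite on simulated fields:
exact counts for non-overlapping nuclei, ≤ 5 % relative error at ≤ 10 %
pairwise overlap, mean centroid error ≤ 2 px.

### Lipid droplets (BODIPY)

`segment_droplets()` runs a fixed sequence with no data-dependent choices:

1. **16-bit cast** — 8-bit input is multiplied by 257; 16-bit input passes
   through unchanged.
2. **Rolling-ball background subtraction**, radius 50 px: the background
   is a grayscale morphological opening with a flat disc (pixel centres
   within the radius). Opening is anti-extensive, so the corrected image
   is non-negative and bounded by the input; structure broader than about
   twice the radius (hazy autofluorescence) is removed, narrower features
   (droplets) survive.
3. **Difference-of-Gaussian enhancement** — the corrected image minus its
   σ = 4 px blur, kept as a *signed* 32-float image. Negative values are
   deliberately not clipped: the threshold is defined on the signed
   difference, and clipping first would silently move the operating
   point.
4. **Fixed manual threshold** of 3 intensity units, `≥` convention.
5. **Particle analysis** — 8-connected components (the de-facto default
   of interactive particle analyzers; 4-connectivity is available), each
   measured for pixel/physical area, centroid, perimeter, circularity and
   equivalent diameter. No size gate is applied by default
   (`min_area_px = 1`).

Touching droplets are *not* split — the workflow has no watershed step —
so count-accurate results presuppose spatially separated droplets; the
simulator enforces a 4 px minimum edge-to-edge gap for exactly this
reason.

**The intensity scale of "threshold 3".** A fixed threshold of 3 only
makes sense when the background noise floor of the difference image sits
well below 3. That is the regime of 8-bit-origin confocal data stored in
16-bit containers (the usual unscaled 8→16-bit conversion), acquired with
enough line averaging that background noise is below one intensity unit.
The threshold is interpreted on the difference image regardless of source
depth.

### Perimeter and circularity

Circularity (4π·area/perimeter², clipped to [0, 1]) implements the
"distinct, circular droplets — not hazy or irregular" criterion. Naive
boundary-pixel counting makes digital discs look non-circular (≈ 0.88),
so the perimeter uses a 4-direction Crofton estimator: boundary crossings
are counted along the horizontal, vertical and two diagonal line families
(diagonals spaced 1/√2), and

P ≈ π/8 · (I_h + I_v + (I_d1 + I_d2)/√2),

which converges to 2πr for rasterized discs. Tests pin discs of radius
≥ 5 px to circularity ∈ [0.85, 1] and a 1-px-wide line to < 0.3.

## Derived metrics

**Adipocyte call.** The manual judgment — positive BODIPY staining
surrounding a DAPI nucleus — is replaced by an explicit, configurable
surrogate (`adipocyte_rule()`): a nucleus is an adipocyte iff at least
`min_droplets` (3) particle centroids lie within `search_radius_um`
(15 µm) of the nucleus centroid *and* their mean circularity is at least
`min_circularity` (0.6). Droplets are not partitioned between cells; a
droplet may count toward several nearby nuclei. This surrogate is
validated only against simulator ground truth and is never claimed to
reproduce human judgments.

**Differentiation efficiency** is the classified-adipocyte count divided
by the nucleus count, per field.

**Five-region cell sampling.** "One nucleus from each of five image
quadrants (top left/right, bottom left/right, centre)" is geometrically
over-determined — four quadrants tile the image — so the field is
partitioned into the four corner quadrants minus a centred square of area
HW/5, which forms the fifth region. One uniformly random, not previously
sampled nucleus is drawn per region (seeded, default seed 0); an empty
region falls back to the unsampled nucleus nearest its centre.

**Per-cell lipid content** is 100 × (droplet-mask pixels inside the cell
region) / (cell-region area). The manual step of tracing the cell
outline has no automated counterpart here; when no traced mask is
supplied the cell region is a disk of `cell_radius_um` (15 µm) around the
nucleus. Simulator ground truth uses the same region definition, so the
fidelity test isolates segmentation error rather than region-choice
error.

**Condition summaries** aggregate per-field metrics as mean ± SEM
(sd/√n) and warn below the conventional n = 3 fields per condition.

## The synthetic-field generator

`generate_field()` renders what the pipelines expect to see, with
complete ground truth:

* **Nuclei**: radially Gaussian blobs (peak 160 above a background of 40;
  sd = radius/2), radii ~ Normal(5, 0.8) µm.
* **Droplets**: anti-aliased discs (amplitude 120), diameters lognormal
  (median 3 µm, σ_log 0.3, truncated to 1–6 µm), placed in an annulus
  6–14 µm around adipocyte nuclei. Placement is uniform in *radius*
  rather than area — droplets nucleate perinuclearly — and a global 4 px
  edge-to-edge minimum gap is enforced. Non-adipocytes receive no
  droplets. The realized adipocyte count is exactly
  `round(fraction × n_cells)`.
* **Haze**: a smooth random field (spatial scale 150 px, well above twice
  the rolling-ball radius; amplitude 0.15 × droplet amplitude) shared by
  all cells, emulating cellular autofluorescence.
* **Noise**: Poisson shot noise (variance = gain × intensity,
  gain 0.008), Gaussian read noise (sd 0.4), then rounding to the 16-bit
  grid. At these defaults the background noise sd is ≈ 0.55–0.67 even on
  top of the haze, so the fixed threshold of 3 sits more than 4 σ above
  the noise floor — the operating regime a fixed manual threshold
  presupposes. `sim_snr()` reports the implied droplet
  peak-to-background-sd ratio (≈ 200 at defaults; the pipelines are
  exercised down to SNR 5 in tests).

**Cell placement.** The default `"lattice"` mode models contact
inhibition in a confluent monolayer: a centred triangular lattice at the
full density pitch (√(2A/(√3·n))), jittered by 1.5 % of the pitch, with a
*hard* minimum centre separation of 0.97 × pitch (violating sites get
their jitter re-drawn). At the default study density — 150 cells per
1024² field at 0.31 µm/px — the pitch is 89.8 px while
annulus-outer + search-radius is 93.6 px, so some droplet sharing between
neighbouring cells is geometrically unavoidable; the placement model
keeps it small enough that the proximity rule's false-positive rate stays
well inside the ±0.05 efficiency tolerance. A `"random"` mode (sequential
placement with a minimum centre distance expressed as a multiple of the
radius sum) provides the overlap-controlled fields used by the
nuclei-counting tests.

**What the generator does not emulate** — and hence what passing tests do
*not* demonstrate about real data: clumped or subconfluent cultures
(nuclei are near-lattice-ordered), optical PSF blur and z-structure,
intensity gradients from uneven illumination, debris and staining
artifacts (an optional debris mode adds irregular low-circularity blobs,
off by default), touching droplets, and any biological coupling between
nucleus morphology and differentiation state. Results on real
micrographs additionally depend on the manual-surrogate parameters
(`adipocyte_rule`, `cell_radius_um`) matching the imaging scale.

**Ground-truth consistency.** Truth areas are defined on the noiseless
pre-quantization droplet mask (pixel centres inside the disc), so
relabelling that mask reproduces the recorded per-droplet areas exactly;
per-cell truth content is computed from the same mask with the same disk
region used by the pipeline.

## Numerical choices

* Gaussian kernels are truncated at 4 σ, so interior mass is conserved to
  < 0.02 % (an impulse blurred at σ = 4 reproduces the closed-form peak
  1/(2πσ²) within 2 %).
* All blurs and the morphological background use reflective boundary
  handling; the morphology is additionally computed on a 2-radius
  reflective pad so both passes see real data everywhere in the crop.
  This avoids the dark-frame artifacts that circular or zero padding
  would inject as spurious difference-image foreground at field edges.
* Grayscale morphology runs on affinely rescaled data in [0, 1]
  (min/max filters commute with affine maps, so the result is exact).
* Thresholding includes the lower bound (`≥ t`).
* Connected components are found on the pixel-adjacency graph; labels are
  renumbered in scan order so output is deterministic.
* Ties in blob detection are broken by (response, row, column) ordering;
  all sampling and simulation randomness flows through explicit seeds,
  and the full pipeline is byte-reproducible given its configuration.
* Degenerate inputs: constant images yield zero-residual backgrounds and
  empty detections (not errors); an empty particle table makes the mean
  droplet size an explicit `"no_particles"` status, never a silent zero;
  empty cell-record lists and zero-area cell regions raise errors.

## Problem sizes used in the validation suite

The acceptance-style tests run the default study conditions: 20 fields
per level at 1024² px and 150 cells for efficiency recovery (true
fractions 0.1/0.4/0.8), 10 fields for lipid-content fidelity, 10
200-nucleus fields for the overlap counting contract, 1000 random 64²
masks against a brute-force flood-fill labelling oracle, and 10,000
seeded draws for sampling uniformity. `scripts/acceptance.R` reproduces
the same quantities at smaller field counts (its JSON reports `n` per
entry).

## Known limitations

* The adipocyte call and the disk cell region are surrogates for manual
  judgments; their parameters are exposed, not learned.
* Touching droplets merge into single particles (no watershed).
* The droplet-sharing analysis above ties the efficiency contract to
  near-confluent, ordered fields; sparse random fields at the same
  density would show a higher false-positive rate.
* Calibration (µm/px) is taken from configuration, not from image
  metadata.
* 2^−ΔΔCt assumes perfect amplification efficiency; efficiency-corrected
  models are out of scope. SEM of fold changes is reported on the fold
  scale (matching the usual "fold change ± SEM" presentation) alongside
  log2-scale summaries; per-replicate fold changes, not Ct-propagated
  errors, feed the SEM.
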
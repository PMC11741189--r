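# adipoquant

Quantification of adipogenic differentiation from two-channel confocal
micrographs of adherent cultures (e.g. iPSC-derived pre-adipocytes):
a DAPI channel marking nuclei and a BODIPY channel marking neutral-lipid
droplets. The package also computes relative gene-expression fold changes
from qPCR Ct tables by the 2^−ΔΔCt method, the companion readout of such
differentiation studies.

## What it computes

For each field (image pair) the pipeline derives:

* **Nucleus count** — the DAPI channel is background-corrected by a flat
  offset (default 50), low-pass filtered (Gaussian, σ = 4 px), and nuclei
  are detected with a Laplacian-of-Gaussian blob detector with
  non-maximum suppression.
* **Lipid-droplet segmentation** — the BODIPY channel is cast to the
  16-bit range, background-corrected with a rolling ball (grayscale
  opening, disc radius 50 px), enhanced as a difference-of-Gaussian
  (image minus its σ = 4 blur, kept signed), thresholded at a fixed
  manual value of 3, and analysed into connected particles with area,
  centroid, Crofton perimeter, circularity = 4π·A/P² and equivalent
  diameter.
* **Differentiation efficiency** = adipocytes / total nuclei, where a
  nucleus counts as an adipocyte iff ≥ 3 circular droplets
  (mean circularity ≥ 0.6) lie within 15 µm of it.
* **Mean droplet size** per field (µm² and equivalent-diameter µm).
* **Per-cell lipid content** — for 5 cells sampled one-per-region
  (four corner quadrants + an equal-area centre), 100 × droplet pixels
  inside the cell region / region area.
* **Condition summaries** — mean ± SEM (sd/√n) across the fields of each
  condition.

A synthetic-field generator (`sim_params()` / `generate_field()` /
`generate_dataset()`) renders DAPI/BODIPY pairs with complete ground
truth — nuclei, droplets, per-cell lipid content, noise and
autofluorescence haze — so the whole chain is validated without any
external data. See the methods vignette
(`vignettes/adipoquant-methods.Rmd`) for the model and design decisions.

## Worked example

```r
library(adipoquant)

# one synthetic field: 150 cells, 40% differentiated, 1024x1024 @ 0.31 um/px
p   <- sim_params(differentiated_fraction = 0.4, seed = 42)
fld <- generate_field(p, field_id = "demo")
res <- process_field(fld$dapi, fld$bodipy, run_config(qc_overlays = FALSE),
                     field_id = "demo")
res$metrics
```

```
#>   field_id n_nuclei n_adipocytes differentiation_efficiency n_particles
#> 1     demo      150           61                  0.4066667         716
#>   mean_droplet_area_um2 mean_equiv_diam_um mean_lipid_content_pct
#> 1              8.777447           3.23349               12.02415
```

All 150 simulated nuclei are found; 716 of the 716 rendered droplets are
recovered as particles; the estimated differentiation efficiency 0.407
sits next to the true fraction 0.4 (the ground truth for this seed is in
`fld$truth`); the mean equivalent droplet diameter ≈ 3.2 µm reflects the
configured lognormal diameter distribution (median 3 µm); and the mean
lipid content is the average droplet coverage of five sampled cells.

For qPCR tables:

```r
ct <- data.frame(
  sample_id = c("c1", "c2", "c3", "t1"),
  group     = c("ctrl", "ctrl", "ctrl", "trt"),
  gene      = rep(c("Fabp4", "18S"), each = 4),
  ct        = c(25.0, 25.2, 24.8, 23.0, 20, 20, 20, 20))
delta_delta_ct(ct, reference_gene = "18S", control_group = "ctrl")$samples
```

```
#>   sample_id group  gene delta_ct delta_delta_ct fold_change
#> 1        c1  ctrl Fabp4      5.0            0.0   1.0000000
#> 2        c2  ctrl Fabp4      5.2            0.2   0.8705506
#> 3        c3  ctrl Fabp4      4.8           -0.2   1.1486984
#> 4        t1   trt Fabp4      3.0           -2.0   4.0000000
```

The treated sample's ΔCt of 3.0 against a control-group mean of 5.0 gives
ΔΔCt = −2 and a fold change of 4; control-group fold changes always have
geometric mean 1 by construction.

A thin CLI wraps the same functions
(`inst/exec/adipoquant simulate|nuclei|droplets|quantify|qpcr`).

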
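# angioquant

Vessel-density quantification and test–retest repeatability analysis for
en-face OCT angiography (OCTA) images of the macula and optic nerve head.

OCTA devices export *en face* images of automatically segmented depth
layers (superficial/deep/outer retina and choriocapillaris for macular
scans; vitreoretinal interface, superficial nerve head, radial
peripapillary capillaries and disc-at-choroid for optic-disc scans). For
clinicians and imaging researchers who need a number per image, this
package computes the **vessel pixel density** — the fraction of region
pixels classified as vessel — per segment and per
superior/inferior/nasal/temporal quadrant, and quantifies how repeatable
that number is across back-to-back scans of the same eye.

## Method at a glance

1. **QC**: a segment image is discarded when it shows more than two
   full-width white lines (motion artifact) or a signal-strength index
   below 40; discards are per segment, not per scan.
2. **De-striping**: frequency-domain Gaussian bandpass
   `H = exp(-2π²σ_h²|f|²) − exp(-2π²σ_l²|f|²)` plus a directional notch
   on the near-zero horizontal-frequency band where stripes live.
3. **Vessel detection (SCIRD)**: correlation with a bank of curved-support
   Gaussian ridge kernels, `G(x₁,x₂) = exp(−x₁²/2σ₁²)·exp(−(x₂+k·x₁²)²/2σ₂²)`
   differentiated twice across the vessel, over scales σ₁, σ₂, curvatures
   k and 12 orientations; the response is the pointwise maximum over the
   bank, then thresholded (top fraction of pixels by default) into a
   binary vessel map.
4. **Regions**: macular quadrants split the frame by its diagonals; disc
   scans use the ellipse inscribed in a manually annotated disc bounding
   box, with the quadrant apex at the ellipse center and nasal/temporal
   labels mirrored between OD and OS.
5. **Repeatability**: per region, with per-subject differences `dᵢ` over
   n subjects — within-subject SD `Sw = √(Σdᵢ²/2n)`, coefficient of
   variation `CV = Sw/overall mean`, repeatability coefficient
   `1.96·√2·Sw`, 95% CIs, and a paired t-test for systematic drift.

A synthetic phantom generator (constant-curvature vessels with exact
ground-truth masks, injectable white lines, paired scans with a controlled
σ_w) makes the whole chain testable without device data. See the vignette
`vignettes/octa-vessel-density.Rmd` for the full model description and
design rationale.

## Worked example

Quantify a noise-free phantom whose true vessel mask is known, using the
truth density as the percentile threshold:

```r
library(angioquant)

ph <- generate_vessel_network(
  phantom_config(grid_size = 160, n_vessels = 8,
                 background_noise_sd = 0, seed = 42))
mean(ph$truth_mask)            # 0.1198  (ground-truth vessel density)

filt <- gaussian_bandpass(ph$intensity)
vm <- binarize_vessels(scird_response(filt, scird_bank()),
                       "percentile", mean(ph$truth_mask))
img <- enface_image(ph$intensity, "macula", "superficial_retina",
                    "OD", "S1", 1)
rs <- build_region_set(img)
density_table(list(superficial_retina = vm),
              list(superficial_retina = rs),
              list(subject_id = "S1", eye = "OD",
                   scan_type = "macula", scan_index = 1))
#>        segment_label   region density vessel_pixels region_pixels
#> 1 superficial_retina  segment  0.1198          3068         25600
#> 2 superficial_retina superior  0.0564           361          6400
#> 3 superficial_retina inferior  0.1416           906          6400
#> 4 superficial_retina    nasal  0.2037          1304          6400
#> 5 superficial_retina temporal  0.0777           497          6400
```

The segment density equals the truth density (the percentile threshold
pins it), the quadrant pixel counts sum exactly to the segment count, and
the detected map overlaps the true mask with Dice 0.843 — the detector is
deciding *where* the vessel pixels are, not just how many.

Repeatability on a simulated cohort at the study scale (47 subjects, two
scans, injected σ_w = 0.02, mean density 0.22):

```r
sim <- generate_paired_scans(
  paired_scan_config(n_subjects = 47, within_subject_sd = 0.02, seed = 1))
sw <- within_subject_sd(sim)
sw                                              # 0.0181
sw_confidence_interval(sw, 47)                  # 0.0145 0.0218
coefficient_of_variation(sw, mean(c(sim$value_1, sim$value_2)))  # 0.081
repeatability_coefficient(sw)                   # 0.0502
```

The estimate recovers the injected σ_w within its confidence interval; a
CV of ~8% at this scale means two scans of the same healthy eye typically
disagree by a few percent of the mean density, and any observed change
smaller than the repeatability coefficient (~0.05 density units) is
within measurement noise.

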
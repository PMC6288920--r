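---
title: "Quantifying OCTA vessel density and its test-retest repeatability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying OCTA vessel density and its test-retest repeatability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angioquant)
```

## The problem

Optical coherence tomography angiography (OCTA) infers blood flow from the
decorrelation between repeated OCT B-scans and exports *en face* images of
device-segmented depth layers of the macula and the optic nerve head. A
natural summary of such an image is the **vessel pixel density**: the
fraction of pixels in a region that belong to vessels. Before density can
be trusted clinically, two things must be in place: a reproducible
image-to-density pipeline, and an estimate of the measurement's
**test-retest repeatability** — how much two densities from back-to-back
scans of the same healthy eye disagree purely through measurement noise.

`angioquant` implements both halves: the quantification pipeline
(de-striping, ridge-based vessel detection, region partition, pixel
counting) and the repeatability statistics (within-subject SD, coefficient
of variation, repeatability coefficient, paired tests), plus a synthetic
phantom generator so that the whole chain can be validated against known
ground truth without access to device data.

## The quantification pipeline

### Quality control

Eye movement during acquisition leaves saturated full-width horizontal
white lines on the en-face image. A segment image is discarded when it has
**more than two** white lines (high motion artifact) or when the device's
signal-strength index (SSI) is **below 40**; discards are per-segment, so
good segments of the same scan stay in the analysis. `count_white_lines()`
operationalizes "white line" as a row that is bright (row mean above the
global mean by `z_thresh = 3` global SDs) *and* uniform across the full
width (within-row coefficient of variation at most `max_row_cv = 0.2`);
consecutive flagged rows merge into one line, so a thick band counts once.
Images without a recorded SSI (synthetic phantoms, anonymized exports)
pass the SSI gate, since the index is device metadata.

### De-striping bandpass

`gaussian_bandpass()` filters in the frequency domain with
`H = exp(-2 pi^2 sigma_high^2 |f|^2) - exp(-2 pi^2 sigma_low^2 |f|^2)`, a
difference of Gaussian transfer functions passing spatial scales between
`sigma_high = 1.5` px (pixel noise) and `sigma_low = 40` px (slow
illumination), bracketing vessel scales of roughly 1–10 px on a ~304 px
3 × 3 mm grid. `H(0) = 0`, so the DC level is removed. An isotropic band
cannot remove a *full-width* stripe, whose energy lives at near-zero
horizontal frequency and all vertical frequencies; a directional Gaussian
notch (`1 - exp(-f_x^2 / (2 (1/n)^2))`, about one cycle per image width)
is therefore multiplied in by default. The FFT treats the image as
periodic; wraparound is harmless for stripes, which span the full width by
definition, and a symmetric-padding option exists for images with strong
borders.

### SCIRD vessel detection

Vessels are curvilinear ridges of varying width and curvature. The
detector correlates the image with a bank of **curved-support Gaussian**
kernels. On the unrotated frame the support is

\[ G(x_1, x_2) = \exp\left(-\frac{x_1^2}{2\sigma_1^2}\right)
   \exp\left(-\frac{(x_2 + k x_1^2)^2}{2\sigma_2^2}\right), \]

a filament elongated along \(x_1\) (scale \(\sigma_1\)) with
cross-section \(\sigma_2\) bent along the parabola \(x_2 = -k x_1^2\);
the kernel is the negated second derivative \(-\partial^2 G / \partial
x_2^2\), rotated by \(\theta\), normalized to zero mean and unit L2 norm.
At \(k = 0\) this reduces to the classical oriented Gaussian
second-derivative ridge kernel; the curvature parameter removes the
assumption of locally straight tubes. The response map is the pointwise
**maximum** of the correlations over the bank, which is what buys
approximate rotation, scale and curvature invariance; unit-norm kernels
keep responses comparable across the bank without further renormalization.

The default bank is \(\sigma_1 \in \{4, 6, 8\}\),
\(\sigma_2 \in \{1, 1.5, 2, 3\}\), \(k \in \{-0.1, -0.05, 0, 0.05,
0.1\}\) px\(^{-1}\), 12 angles evenly spaced over \([0, \pi)\), kernel
half-size \(\lceil 3 \max \sigma_1 \rceil = 24\) px — 720 kernels covering
capillary-to-arteriole widths at 3 × 3 mm en-face resolution. Correlation
uses symmetric boundary extension; the FFT backend is required to match
direct spatial correlation to within 1e-6 relative, and the test suite
holds it to that.

The binarization rule is deliberately exposed rather than hidden: the
default keeps the top `threshold_param = 0.25` fraction of response pixels
(`percentile` method; ties at the cutoff broken by row-major pixel order
so the mask cardinality is exact and deterministic), and the threshold is
recorded alongside the output. A percentile threshold makes the resulting
density invariant to any global intensity rescaling upstream. With a
percentile threshold the *segment* density is largely pinned by the
threshold itself; what the detector determines is **where** those pixels
are — quadrant densities, and the overlap with real vasculature.

### Regions

Macular scans are analysed over the full square frame with the quadrant
apex at the image center. For disc scans an observer supplies the minimum
axis-aligned bounding box of the optic disc; the inscribed ellipse
approximates the disc border, and its center becomes the quadrant apex,
anchoring the partition on the anatomy rather than on scan centration.
The diagonal and anti-diagonal lines through the apex split the frame
into superior, inferior, nasal and temporal sectors; nasal/temporal labels
mirror between OD and OS. Because device exports do not guarantee an
un-mirrored orientation, the convention "OD nasal = image right" is a
config switch (`region.od_nasal_side`).

Two open geometric choices are resolved as follows:

* **Boundary pixels.** Pixels exactly on a dividing line (which happens
  whenever the center offsets satisfy \(|dx| = |dy|\), including the
  common half-integer-center case) are assigned by treating the sectors as
  half-open angular intervals: superior is \([-135°, -45°)\), and so on
  around. This is deterministic, tiles the grid exactly (asserted on
  every call, not only in tests), and splits an even-sided grid with a
  half-integer center into four *equal* quadrants — the natural reading
  of "four equal quadrants". A rule that sends whole diagonals to a
  single sector would instead inflate two quadrants by a full diagonal's
  worth of pixels.
* **Disc interior.** Whether density should include the avascular disc
  interior is not obvious; the default includes the full frame (matching
  the macular convention) and a switch (`region.disc_interior`) can
  exclude, or restrict to, the ellipse interior. The ellipse is always
  computed and stored for provenance.

### Density

`vessel_density()` is an exact pixel ratio; per scan, `density_table()`
emits five regions (segment + four quadrants) per segment in a fixed
order, and asserts on every run that segment pixel counts equal the sum
of quadrant counts.

## Repeatability statistics

With two scans per eye, let \(d_i\) be the per-subject difference of a
region's densities. The package uses the standard Bland–Altman machinery:

* within-subject SD: \(S_w = \sqrt{\sum_i d_i^2 / 2n}\), the square root
  of the one-way within-subject mean square;
* coefficient of variation: \(CV = S_w / \bar{x}\), with \(\bar{x}\) the
  mean over **both** scans' values (the natural reading of "overall
  mean"); reported as a percentage in display layers;
* repeatability coefficient: \(1.96\sqrt{2}\,S_w\), the 95% bound on
  \(|d|\);
* paired t-test on the \(d_i\) for systematic drift between scans.

With \(m = 2\) replicates the within-subject sum of squares has
\(n(m-1) = n\) degrees of freedom, so \(n S_w^2 / \sigma_w^2 \sim
\chi^2_n\). The default CI is the matching large-sample form
\(S_w (1 \mp 1.96 / \sqrt{2n})\) (an SD with \(\nu\) df has standard
error \(\approx \sigma / \sqrt{2\nu}\)); an exact \(\chi^2_n\) pivot is
available via `stats.ci_method = "chisq"`. Simulation at the scale this
package targets (47 subjects, \(\sigma_w = 0.02\), mean 0.22) puts the
normal CI's empirical coverage near 94%, within the usual [90%, 98%]
acceptance band for an approximate interval.

Two small conventions worth stating: no multiplicity correction is
applied by default across the ~40 regional paired tests (matching
standard practice in repeatability studies; a Benjamini–Hochberg column
is available via `adjust = TRUE`), and under-filled groups (< 2 usable
pairs) are emitted as `NA` rows rather than dropped, so report structure
is always predictable. One arithmetic caveat: when a published table
rounds \(S_w\) to 3 dp before multiplying by \(1.96\sqrt{2}\), the
printed repeatability coefficient can disagree with the printed \(S_w\)
in the third decimal (e.g. 0.078 → 0.216, not 0.217; 0.028 → 0.078, not
0.076). `angioquant` always computes from unrounded values.

## What the synthetic generator does and does not emulate

`generate_vessel_network()` renders constant-curvature arcs (random
start, direction, curvature, half-width) with Gaussian cross-sectional
profiles on a square grid, records the exact truth mask (pixels within
the half-width of a centerline, computed from analytic arc distance),
then adds Gaussian speckle and, optionally, saturated one-pixel white
lines on non-adjacent rows. Constant-curvature arcs deliberately exercise
the detector's \(k\) parameter. `generate_paired_scans()` draws a true
density per subject from
\(\mathcal{N}(\mu, \sigma_b)\) and two observations with independent
\(\mathcal{N}(0, \sigma_w)\) errors, truncated to \([0,1]\) (a slight
bias at the extremes, accepted rather than resampled away). Defaults are
the study scale: 47 subjects, \(\mu = 0.22\), \(\sigma_w = 0.02\).

Not emulated, by design: OCT speckle physics and decorrelation
statistics (noise here is additive Gaussian, the simplest model that
stresses thresholding), projection artifacts between layers, realistic
branching vascular trees, and the foveal avascular zone. Passing tests on
phantoms therefore demonstrate that the pipeline's geometry, filtering
and statistics are correct — not that its absolute densities match any
particular device's output on real eyes. Real-data absolute densities
additionally depend on the binarization threshold, which the original
acquisition software does not publish; this package exposes it as
configuration and records it in output metadata.

## Numerical choices and validation sizes

* FFT correlation must agree with direct spatial correlation to 1e-6
  relative; kernels are zero-mean and unit-L2 to 1e-9.
* Percentile binarization uses exact counting with a stable row-major
  tie-break, so results are platform-independent.
* Degenerate paired tests (all differences zero) return p = 1 with a
  `degenerate` flag instead of erroring.
* All generators are bit-reproducible under a fixed seed.
* Validation problem sizes were chosen so the full suite runs comfortably
  on a laptop: phantoms of 60–160 px (the 160 px phantom runs the full
  720-kernel default bank), repeatability simulations of 200 replicates
  at the 47-subject study scale, and brute-force geometric oracles on
  100 × 100 grids.

## Limitations

The white-line detector's global z-score becomes conservative when
stripes occupy a large fraction of a small image (they inflate the global
SD they are compared against); at realistic grid sizes (≥ 300 px, a few
stripes) this is immaterial. The ellipse approximation inherits any
observer bias in the bounding box. And because the published pipeline's
threshold and bank parameters are unknown, cross-study comparison of
absolute densities should go through the repeatability statistics, which
are threshold-stable, rather than raw density values.
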
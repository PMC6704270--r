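---
title: "Methods: myelination morphometry and its validation by parameter recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: myelination morphometry and its validation by parameter recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myelinmetrics)
```

`myelinmetrics` implements the measurement chain used to quantify
developmental myelination in mouse white matter: suprathreshold myelin
coverage, reporter-masked MBP intensity with per-image outlier rejection,
Node of Ranvier (NoR) length from paranodal line profiles, Olig2/CC1 cell
densities, and g-ratio morphometry of EM cross-sections, together with the
three statistical procedures conventionally applied to these readouts. This
vignette is the package's account of each model, the tunable parameters and
their defaults, the synthetic scenes used for validation, and the numerical
and design decisions taken where the conventional workflow leaves choices
open.

## Image model and conventions

Images are `calibrated_image` objects: one non-negative intensity array per
*channel role* (`TDTOMATO`, `MBP`, `CASPR`, `DAPI`, `OLIG2`, `CC1`, `EM`)
plus a pixel size in µm (fluorescence) or nm (EM). Roles, not channel
numbers, name what a measurement reads, so a pipeline written against roles
survives changes in acquisition order. Conventions used throughout:

* pixel coordinates are 0-based, `(x, y) = (column, row)`, with pixel
  centres at integer coordinates;
* intensities are handled as doubles regardless of the on-disk integer type;
  TIFF I/O stores 16-bit integers and round-trips synthetic scenes
  bit-exactly;
* confocal pixel size is a **required user input**: objective magnification
  alone does not determine it, and no default could be defended.

Maximum-intensity projection (`max_project()`) refuses more than five
slices. The per-node projection convention this mirrors uses at most five
interleaved confocal slices; projecting more would inflate out-of-focus
Caspr signal into the profile, so the cap is enforced rather than advisory.

## Line profiles and node length

A measurement path is an open polyline with an odd pixel `thickness`
(default 5, slightly thinner than typical paranode labelling). The profile
sampler walks the path at 1 px arc-length steps and averages `thickness`
bilinearly interpolated samples perpendicular to the local direction. The
sampling step is not part of the measurement definition; because the
half-maximum crossing is later located by sub-pixel linear interpolation,
halving the step moves recovered lengths by far less than the stated
tolerances (the Gaussian-peak oracle below quantifies this).

`node_length_from_profile()` implements the half-maximum rule:

1. the global interior minimum of the profile splits it into two paranode
   sides; the peak on each side is the highest sample (ties broken toward
   the profile ends — the wider node is the conservative error);
2. the valley is the minimum between the two peaks; each paranode's
   half-maximum level is `valley + (peak − valley)/2`. Subtracting the
   valley before halving makes the measurement exactly invariant to adding
   a constant to the whole profile, and the per-paranode levels (rather
   than one shared level) follow the convention of computing the maximum
   for each paranode separately;
3. the crossing is searched from each peak *toward the valley* and the
   first bracketing sample pair is linearly interpolated — i.e. the
   crossing nearest the peak, which is robust to noise wiggles on the
   valley floor;
4. the node length is the distance between the two crossings.

Consequences a user should know. The rule presumes the measurement line is
drawn *over the paranode pair* — starting and ending on or inside the
paranodal signal — exactly as one draws it interactively. A line extended
far into dark tissue places the global interior minimum at the dark ends
and the measurement correctly refuses. Each failure mode raises a distinct
condition class (`myelin_node_no_peaks`, `myelin_node_flat`,
`myelin_node_no_crossing`, `myelin_node_degenerate`) so batch runs can
report "no quantifiable node" per candidate rather than aborting; in real
material a substantial fraction of sections contains no quantifiable node,
and the batch interface (`measure_nodes()`) preserves that information. No
smoothing is applied by default; an optional odd-window moving average is
available for low-SNR batches and is recorded in the result.

Candidate validation (`validate_candidate()`) encodes the selection rule
that only nodes on labelled axons are measured: suprathreshold tdTomato
under the central third of the path, suprathreshold Caspr under both outer
thirds, and suprathreshold MBP within a 2 µm window beyond both path ends.

## Thresholding, coverage and ROI intensity

Binarization is unspecified in most published workflows; the package
defaults to Otsu's criterion with an explicit fixed-threshold override, and
records method and realised threshold in the mask provenance. Otsu is
implemented as an exact search over the observed intensities (foreground =
intensity ≥ t, maximizing between-class variance); on data with an empty
intensity gap between classes the criterion is flat across the gap, so two
correct implementations may report different thresholds while inducing the
same mask — provenance therefore records the realised value.

Coverage follows the 2-SD rule: the background mean and SD are pooled over
all supplied signal-free ROIs across images (population SD, divide-by-n;
the choice is recorded so the sample-SD alternative is one flag away), and
a pixel is counted when its intensity is **strictly** above
`mean + k_sd * sd` (k_sd default 2; "above" is read as exceeding, ties are
background). The denominator is all pixels of the image — no tissue
masking — because the statistic is defined as the percentage of each image.
Whether pooling should instead be per-image is left to the caller: pooled
is the default and the per-image alternative is a separate
`estimate_background()` call per image.

ROI intensity (`roi_intensity()`) is deliberately symmetric in its roles:
reporter-masked MBP for callosal analysis, MBP-masked MBP for the striatal
variant where myelinated regions are quantified directly. An empty mask is
an error distinct from zero intensity ("no labelled fibres"), not a silent
zero. The outlier filter measures each image's MBP mean in a 200 × 125 px
reporter-free box and discards images deviating **strictly** more than one
population SD from the cohort mean of box means; with two images the two
deviations are equal, so nothing can be discarded, and the filter can never
discard all images. Box placement is user-supplied (it is manual in
practice); `propose_box()` is a labelled convenience that minimises
reporter content via an integral image, not a fidelity claim.

## Cell detection and double-positive counting

"Noise tolerance" in the classic Find Maxima tool is topographic
prominence: a local maximum counts when it rises strictly more than the
tolerance above the highest saddle that connects it to higher terrain. The
package implements this as a single descending-intensity union-find sweep
(in C++ via Rcpp; the per-pixel loop is the one place the field's image
packages also drop to compiled code), with summit plateaus reported once at
their centroid and the global maximum measured against the image minimum.
Defaults are the midpoints of the conventional ranges: 110 for Olig2,
90 for CC1. Tied summit heights are a convention, not a property: a tied
peak whose connecting saddle is within tolerance is absorbed into its
neighbour, as the reference tool behaves.

Double-positive counting is object-based: a **maximum** one-to-one matching
(Kuhn's augmenting-path algorithm) between the two centre sets with a
pairwise distance cap, 5 µm by default (about half a nuclear diameter).
Greedy nearest-first pairing is not used because it is not always
maximum-cardinality; the tests check the implementation against exhaustive
optimal matching on small sets. Pixel-correlation colocalization
coefficients are out of scope — a density of double-positive *cells* is an
object count, and object matching is the only reading consistent with it.

## g-ratio morphometry

Input is expert annotation — labelled masks (inner = 2k, myelin ring =
2k + 1 for axon k) or JSON contours — not automated segmentation, matching
how EM quantification is actually performed. Diameters are area-equivalent:
`d = 2·sqrt(A/π)`, robust to non-circular cross-sections (a caliper/Feret
alternative would be systematically larger on elliptical profiles; the
choice is recorded in the result type). g = d_inner/d_outer is
dimensionless and exactly invariant to rotation, translation and pixel-size
rescaling. ROI membership is decided by the fibre (outer) centroid falling
inside the rectangle — default 32.5 µm × 42.5 µm, the largest box that fits
the dorsal corticospinal tract at the conventional 8 nm pixel — which
avoids double-counting fibres cut by ROI edges across tiles.

## Statistics

The three procedures are implemented from their definitions, with base R's
`t.test`/`wilcox.test` used as independent cross-checks in the tests:

* `welch_t()`: t = (m₁ − m₂)/√(s₁²/n₁ + s₂²/n₂), Welch–Satterthwaite df,
  two-sided p;
* `mann_whitney()`: U from midranks; exact two-sided p
  `2·min(P(U ≤ u), P(U ≥ u))` (capped at 1) by full enumeration when
  n₁ + n₂ ≤ 16 without ties, otherwise the normal approximation with tie
  correction and 0.5 continuity correction; the mode can be forced;
* `anova_bonferroni()`: equal-variance one-way F (via `stats::oneway.test`)
  followed by all pairwise Welch comparisons with p multiplied by the
  number of pairs, capped at 1; the family size is recorded in the output.

The unit-of-analysis convention is preserved and recorded on
`group_sample`: per-brain means for t/ANOVA, individual node measurements
for the rank test. Pooling nodes across brains ignores within-brain
correlation and therefore anti-conservatively narrows the rank test's null;
the package reproduces the convention because it is the convention, without
endorsing it — a hierarchical model is deliberately out of scope.

## Synthetic scenes: what they emulate and what they do not

Each generator seeds the RNG from its `seed` argument, quantizes to integer
intensities (so determinism survives file round-trips across platforms),
and returns a ground-truth record sufficient to re-derive every planted
quantity.

* `make_node_scene()` renders a straight tdTomato axon, two Caspr plateaus
  of length 2 µm separated by the true gap, and flanking MBP, all evaluated
  analytically as Gaussian-blurred boxcars (along-axis PSF σ = 0.1 µm,
  radial σ = 0.15 µm) — for a symmetric blur the half-maximum of a plateau
  edge sits exactly on the geometric edge, so the planted gap *is* the true
  nodal length. Noise is shot-like: Gaussian with variance proportional to
  the local signal. Because "SNR" is ambiguous, it is defined here as
  (peak − background)/noise-SD *at the peak*; `snr = Inf` disables noise.
  Defaults: amplitude 200 over background 10, SNR 10, 0.05 µm pixels,
  z-step 0.482 µm for stacks.
* `make_axon_field()` draws smooth random fibre curves, ensheathes a
  contiguous fraction of each, and — when a coverage target is given —
  tops up or thins the bright-pixel set to exactly
  `round(target · n_pixels)` pixels. Background noise is bounded (discrete
  uniform ± 5, SD √10), so no background pixel can cross the
  mean + 2 SD threshold (≈ background + 6.3) and planted coverage is
  recovered *exactly*, as the integer-count tests assert. A fibre-free
  rectangle is reserved and recorded for background estimation.
* `make_nucleus_field()` plants Gaussian blobs (σ = 3 px) at
  minimum-separated integer centres, sharing a prescribed fraction between
  the two marker channels.
* `make_em_field()` packs non-overlapping annuli with truncated-normal
  inner diameters (default 1000 ± 250 nm) and g (default 0.8 ± 0.06,
  truncated to (0.5, 0.95)), largest first, at continuous centres — the
  expected pixel count of a randomly placed disc equals its area, so
  pixel-counted diameters are unbiased. The per-axon g spread of 0.06 is
  the field-typical value; a much larger spread is unphysical for a
  quantity bounded in (0, 1) and, under truncation, would drag the realised
  cohort mean well below the nominal one. The default 20 axons per
  1024 px tile corresponds to a tissue-like ~40 % areal fill; larger
  cohorts are accumulated over tiles.

What passing these tests shows — and does not. Recovery on these scenes
demonstrates that the *measurement chain* is correct: geometry, calibration,
interpolation, thresholds, matching, statistics. It does not demonstrate
robustness to what the generators deliberately omit: curved or crossing
axons, heterogeneous background, bleed-through between channels, anisotropic
PSFs, touching nuclei, non-annular myelin. Real-data use still requires the
experimenter's candidate selection and annotation, exactly as in the
interactive workflow.

## Validation scale and the power property

The test suite and `scripts/acceptance.R` run at sizes chosen so the whole
validation completes in minutes on one core: 256–512 px fluorescence
fields, 1024 px EM tiles, 20 seeds per planted gap, 2000-replicate null
calibration, and a 100-replicate end-to-end power experiment; the EM group
comparison accumulates ~2200 axons per cohort at a coarsened 32 nm raster.
These are the package's validation conditions, stated here so they can be
scaled up by anyone wanting tighter Monte-Carlo error.

One validation property deserves honesty in advance. The end-to-end power
experiment draws two node cohorts of 116 and 66 nodes with true mean gaps
1.6 vs 1.4 µm and per-node SDs calibrated so the cohort SEMs are ≈ 0.07 and
0.09 µm — the scale reported in comparable in-vivo node datasets — renders
every node as an image, measures it, and applies the per-node rank test.
At that calibration the standardized group difference is
0.2/√(0.07² + 0.09²) ≈ 1.75, so the two-sided test's power at α = 0.05 is
analytically ≈ 0.42 (and slightly lower for truncated-normal gaps once
measurement noise is added). A single observed p < 0.05 at these sizes is
therefore an unsurprising but not reliably repeatable event; the
acceptance script reports the realised rejection fraction
(`node_cohort_power_fraction`) rather than presuming it high, and the
corresponding acceptance test documents the gap between this calibration
and an 80 %-power design (which would need cohort SEMs roughly 0.045 and
0.055 µm).

## Known limitations

* No automated discovery of node candidates or background ROIs; both are
  user-supplied, as in the interactive workflow.
* No hierarchical modelling of the brain/section/node nesting (see above).
* Proprietary microscope formats, registration, deconvolution and automated
  EM segmentation are out of scope; TIFF/OME-TIFF in, CSV/JSON out.
* The g-ratio is reported per fibre without knowing each axon's
  experimental-group identity (reporter labelling rarely survives EM
  fixation); a population-level group effect can be demonstrated, but
  axon-level attribution cannot.
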
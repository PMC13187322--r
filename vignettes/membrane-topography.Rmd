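---
title: "Membrane topography and enrichment quantification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane topography and enrichment quantification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(protrusionQuant)
```

## The problem and the model

T-cell surfaces are covered by thin actin-rich protrusions (microvilli,
~100–300 nm wide, ~1–3 µm long) that initiate contact with target cells.
At 70 nm confocal pixels a protrusion is a bright ridge a few pixels
wide; the cell body membrane is a thin bright shell around a dimmer
interior. The pipeline turns each frame of a multi-channel time lapse
into a set of binary masks and reduces protein redistribution to four
region statistics, every one of them a ratio or difference of region
means and therefore independent of acquisition gain:

* enrichment `E(R) = mean(I|R) / mean(I|M)` with `M` the whole plasma
  membrane;
* relative enrichment, `E` normalised by an evenly distributed membrane
  marker (SNAP-CAAX) imaged in the same cell — this cancels geometric
  biases shared by all channels (blur, mask width, flank pixels), which
  is precisely why the marker is carried along;
* contact relative enrichment, `E(R ∩ target)/E(R \ target)` (the
  membrane mean cancels);
* membrane-bound signal, `E(R ∩ target) − E(R \ target)`, computed per
  region class because protrusions and body membrane have different
  apparent brightness; its "relative" form divides by the CAAX
  enrichment with ratio-propagated uncertainty.

Standard errors accompany every metric: region means carry
`sd/sqrt(n)` over pixels, differences add variances, ratios add relative
variances, and a zero-valued numerator keeps `sem(a)/|b|`.

## Segmentation procedure and its assumptions

Each channel is background-subtracted (rolling ball, radius 50 px) and
blurred (σ = 1 px). The segmentation image is the pixel mean of the
membrane-reference and receptor channels (or whichever of the configured
roles are present), blurred at σ = 2 px. Two streams follow:

1. **Inner body.** Dark regions fully enclosed by brighter surroundings
   are enhanced, thresholded (Otsu by default), area-filtered
   (≥ 5000 px² ≈ a 4 µm-radius cell), hole-filled, and the largest
   component kept. Frames with no detectable enclosed interior (high
   intracellular signal) are flagged and discarded — a returned flag,
   never an error. The default enhancement fills grayscale holes by
   border-seeded morphological reconstruction and returns
   `filled − image`: it is parameter-free and exactly zero outside
   enclosed basins. A `rolling_ball` dialect (background subtraction of
   the inverted image) is kept as a configuration option; note that a
   ball smaller than the enclosed interior treats the interior itself as
   background, so that dialect only isolates holes narrower than the
   ball.
2. **Membrane structures.** The tubeness score is
   `max(0, −λ₂)·σ²` from the Hessian eigenvalues of the σ-smoothed image
   (σ = 1 px default): high on bright ridges, identically zero on flat
   regions. The auto-threshold is computed over the *positive support*
   of the response — the zero background class would otherwise dominate
   the 256-bin histogram and drag the threshold to the noise floor.

Mask algebra then defines the regions: protrusion candidates are the
thresholded ridges minus the 9 px-dilated inner body, clipped to the
35 px neighbourhood, with single-pixel objects discarded; the body
membrane is ridges minus inner body minus protrusions; the whole
membrane is their union. All dilations use exact Euclidean disc
structuring elements (distance-transform based), and connected
components default to 8-connectivity with deterministic first-scan
labelling, so largest-component ties break reproducibly.

Target cells are segmented per frame with a scalar moment-preserving
("Moments") threshold computed once from the preprocessed *last* frame,
where the target is fully present; applying the scalar per frame lets
the mask follow target motion. Time zero is the first frame whose
contacting membrane has at least `min_contact_px` (default 1) pixels;
frames discarded upstream carry no contact information and are skipped.
Receptor clusters are connected components of the receptor image,
normalised by its per-frame whole-membrane mean (per-frame, so
photobleaching does not bias later frames), strictly above 2, with areas
in [5, 100] px inclusive; each cluster is assigned by larger overlap
with the protrusion or body mask (ties to the protrusion, the smaller
region), and off-membrane components stay unassigned.

## Numerical choices

* **Thresholds.** All automatic thresholds work on a 256-bin histogram
  spanning the data range, making the resulting masks exactly invariant
  to positive rescaling. The Moments method is implemented as the
  discrete moment-preserving criterion itself: for every candidate
  level, the two representative gray values preserving mean and variance
  are computed in closed form and the level minimising the third-moment
  mismatch is selected. The ImageJ shortcut (closed-form `p0` crossing)
  agrees to within one gray level; the discrete rule is the one checked
  against an independent brute-force oracle in the tests.
* **Rolling ball.** Grayscale opening with a ball structuring element,
  with the Fiji shrink factors (2/4/8 for radii above 10/30/100) and
  block-minimum downsampling. The ball height is calibrated to the image
  dynamic range (radius/255 of the range, the 8-bit convention). That
  calibration makes the operator positively homogeneous, so the whole
  pipeline is exactly scale invariant — a property the test suite checks
  to 1e-9. The estimate is clamped below the image, which also makes the
  subtraction idempotent on flat residuals.
* **Boundary handling.** Convolutions use reflective padding (no rim
  artefacts on shell-shaped cells); morphology clamps (replicates) edge
  pixels.
* **Degenerate inputs.** Constant images yield degenerate histograms and
  are handled explicitly (inner-body detection fails gracefully; a
  constant image has zero tubeness everywhere). Empty sub-masks yield
  missing values — never zeros — and missing frames are counted in the
  window aggregation.
* **Windows.** "First minute" aggregation is the inclusive interval
  [0, 60] s relative to time zero, so a frame at exactly 60 s is
  included; 4 s and 15 s acquisitions pool naturally because selection
  is by time, not frame index.

## The synthetic scenes

`generate_scene()` renders what the analysis assumes: a convex cell body
(radius 85 px ≈ 6 µm by default) whose membrane is a 3 px bright shell,
straight capsule protrusions (3 px wide, 12–28 px long, non-overlapping
random angles or user-fixed angles), a half-plane target entering from
the right whose first membrane overlap happens exactly at the configured
onset frame, per-channel region factors, contact-site receptor clusters
appearing a configurable delay after contact, Gaussian optics blur
(σ = 1 px), and Poisson + Gaussian noise with an independent
counter-based substream per (frame, channel). The membrane baseline is
1 intensity unit, so `photon_scale = 100` gives a membrane SNR of ~10
and 25 gives ~5.

Two semantic choices deserve emphasis:

* **Factors are target enrichments.** A protrusion factor *f* requests
  that the region's mean be *f* times the whole-membrane mean; the
  renderer compensates the intensity of the factor-1 regions so the
  request is met exactly in the noiseless limit. The naive reading
  (multiply the region by *f* and leave the rest alone) cannot yield an
  enrichment of *f*, because the normalising membrane mean contains the
  factored region itself; it also caps the achievable enrichment at
  1/(area fraction), which is why the generator raises an explicit
  "infeasible" error when `f × membrane-area-fraction ≥ 1`. Contact
  factors are instead multiplicative on their parent region, so a
  planted exclusion factor is recovered exactly as the contact relative
  enrichment of the protrusion (the membrane mean cancels).
* **Render follows physics, masks follow the analysis convention.** A
  protrusion carries its factor along the whole capsule, root included,
  while the truth masks split protrusion from body membrane at the 9 px
  margin — the same convention the pipeline applies. Switching the
  rendered factor exactly at the margin circle would make the measured
  relative enrichment biased toward 1 by ~10% whenever the pipeline's
  inner-body estimate differs from truth by a pixel, an artefact of the
  scene rather than of the method. One consequence: the truth
  contact-value at the *body* membrane is a mixture when capsule roots
  are in contact; the protrusion-side truth stays exact.

Cluster centres are sampled at least 4 px away from the protrusion/body
margin circle so that every planted cluster has an unambiguous truth
location under the majority rule. Exact planted areas are only
meaningful on an unblurred render, so cluster-recovery validation runs
with `psf_sigma_px = 0`, zero noise, and preprocessing disabled;
everywhere else the defaults stay on.

What the scenes do **not** emulate: curved or branching microvilli,
protrusion motion between frames, 3D geometry and defocus, STED-scale
structure, spectral bleed-through, photobleaching, or target-derived
protrusions. A green recovery test therefore establishes that the
implementation measures what it defines, on geometry satisfying its
assumptions — not that those assumptions hold for any given microscope.

## Known limitations

* The protrusion mask is wider than the geometric capsule: the σ = 2 px
  segmentation blur (plus optics) spreads a 3 px ridge to ~5 px at any
  standard threshold of the tubeness response. Recall against the exact
  truth is 1.0 in the validation scenes, but pixel-precision against the
  exact capsule plateaus near 0.7; the property suite therefore scores
  precision against the 1 px-dilated truth — the localisation the blur
  chain physically supports. Enrichment statistics are insensitive to
  this widening because the reference channel shares it.
* Protrusions are quantified as per-frame region aggregates; individual
  protrusions are not tracked over time.
* The CAAX reference for relative membrane-bound signal is computed
  in-run when a reference channel is present; otherwise it must be
  supplied (`caax_reference_enrichment`), mirroring reuse of a reference
  dataset, and no attempt is made to infer it.
* Configuration files are JSON (no YAML dependency in the supported
  stack); every CLI flag overrides the file.
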
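# protrusionQuant

Quantitative image analysis of T-cell plasma-membrane topography in
live-cell fluorescence time lapses.

T cells are covered in thin actin-rich protrusions (microvilli) that make
first contact with target cells. Understanding whether receptor triggering
is driven by protein pre-enrichment in these protrusions or by
contact-driven reorganisation (receptor clustering, kinase recruitment,
phosphatase exclusion) requires segmenting the membrane into protrusions
vs the main body membrane and measuring protein redistribution over time.
`protrusionQuant` reimplements such a pipeline as a tested, reusable R
package for multi-channel 2D time lapses (confocal, one Z-slice, ~70 nm
pixels) of CAR T cells engaging target cells, together with a
ground-truthed synthetic-scene generator so that every stage can be
validated without microscopy data.

## The statistics at its core

For a protein imaged in a channel, with a membrane region *R* (protrusions
or main body membrane) and the whole plasma membrane *M*:

* **Enrichment** `E(R) = mean(I | R) / mean(I | M)` — how concentrated the
  protein is in the region relative to the whole membrane.
* **Relative enrichment** `E(protein, R) / E(CAAX, R)` — normalised by an
  evenly distributed membrane marker (SNAP-CAAX) imaged in the same cell;
  1 means no preference, values > 1 mean enhanced localisation.
* **Contact relative enrichment** `E(R ∩ target) / E(R \ target)` — the
  redistribution of a protein between target-contacting and
  non-contacting parts of a region (used e.g. for CD45 exclusion).
* **Membrane-bound signal** `E(R ∩ target) − E(R \ target)` — the
  recruitment readout for cytoplasm-dominated proteins (ZAP-70), computed
  per region class; **relative membrane-bound** divides by the CAAX
  enrichment, with standard errors propagated through every difference
  and ratio.

Segmentation follows the two-stream design of the original analysis:
dark-hole enhancement → inner cell body; tubeness (Hessian ridge)
filtering → thresholded membrane structures; mask algebra with 9 px and
35 px dilations → protrusion, body-membrane and whole-membrane masks.
Target cells are thresholded with the moment-preserving ("Moments")
method computed on the last frame; time zero is the first frame with a
detected contact; receptor (CAR) clusters are components of the
membrane-normalised receptor image above 2 with areas in [5, 100] px.

## Worked example

Simulate a CAR T cell whose protrusion contacts exclude a protein to 0.6×
(a CD45-like exclusion), then run the full pipeline:

```r
library(protrusionQuant)

p <- scene_params(
  field_size_px = 256, body_radius_px = 60, n_frames = 6,
  target = list(speed_px_per_frame = 6, onset_frame = 3),
  channels = list(membrane_reference = channel_factors(),
                  receptor = channel_factors(),
                  protein  = channel_factors(protrusion_contact = 0.6),
                  target   = channel_factors()),
  seed = 99)
sim <- generate_scene(p)
ev  <- run_event(sim$stack, pipeline_config(), cell_id = "demo")
ev
#> event_result 'demo' (rep1): 6 frame(s), 0 discarded, t0 = 3

subset(ev$timecourse, metric == "contact_relative_enrichment" &
       region == "protrusion" & channel_role == "protein" & !is.na(value))
#>  frame t_s     value        sem
#>      3   0 0.2825109 0.02127860
#>      4   4 0.6209285 0.03488769
#>      5   8 0.6080302 0.02208437
#>      6  12 0.6397586 0.01738327

w <- aggregate_window(ev$timecourse, metric = "contact_relative_enrichment",
                      region = "protrusion", channel_role = "protein",
                      window_s = c(0, 60))
sprintf("first-minute mean: %.3f +/- %.3f (n = %d frames)",
        w$value, w$sem, attr(w, "n"))
#> "first-minute mean: 0.538 +/- 0.085 (n = 4 frames)"
```

The pipeline detects first contact exactly at the planted onset (frame 3)
and recovers the planted 0.6× exclusion once the contact exceeds a few
pixels (the frame-3 value rests on a single-pixel first touch, which is
why its uncertainty matters). `ev$contact_fractions` shows the contact is
protrusion-mediated at first (100%) and later shared with the main body
membrane (34%/66%); `summarise_events()` pools events into superplot-style
per-replicate means with paired/unpaired t tests.

A command-line interface covers batch use:

```sh
exec/protrusion-quant simulate --out scene/ --seed 7
exec/protrusion-quant quantify --input scene/stack.tif \
    --roles membrane_reference=1,receptor=2,target=3 --out out/
exec/protrusion-quant summarise --inputs out/metrics.csv --out summary.json
```

## Package layout

* `R/` — image model and TIFF I/O, preprocessing, thresholds, morphology,
  membrane/contact/cluster segmentation, enrichment metrics, synthetic
  scenes, pipeline orchestration, CLI.
* `src/kernels.cpp` — separable convolution, grayscale ball morphology,
  exact Euclidean distance transform, connected components, morphological
  reconstruction.
* `vignettes/membrane-topography.Rmd` — the methods vignette: model,
  assumptions, parameter choices, what the synthetic scenes do and do not
  establish.
* `tests/testthat/` — unit, property and acceptance suites with
  independent oracles.
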
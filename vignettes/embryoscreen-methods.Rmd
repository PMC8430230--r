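---
title: "Methods: automated analysis of zebrafish embryo screening plates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated analysis of zebrafish embryo screening plates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

High-content screens image one anaesthetised zebrafish embryo per well of a
96-well alignment plate, in brightfield plus one or two fluorescence
channels. Each well is covered by four overlapping fields along its long
axis, and each field is a five-plane z-stack (50.6 µm between planes), so a
full plate is 3840 raw tiles. The biological read-outs are per-embryo:
counts of labelled cells in an anatomical region (e.g. haematopoietic
stem/progenitor cells, HSPCs, in the caudal haematopoietic tissue at the
base of the tail), whole-fish fluorescence intensity or area, or
morphometrics such as eye size. Two practical obstacles dominate:

* **Orientation.** Only embryos lying on their side with the whole body in
  view are analyzable. A small fraction per plate (typically below 5%) lie
  on their back, are only partially in the imaging window, or the well is
  empty. These must be excluded automatically — manual triage would negate
  the throughput, and subjective exclusion skews statistics.
* **Autofluorescence.** Larvae at these stages autofluoresce strongly over
  the head and yolk. A single global threshold that clears the haze also
  deletes the dim cell class of interest (GFP-lo HSPCs, as opposed to the
  bright GFP-hi thrombocytes), so detection must reference the local
  background.

`embryoscreen` implements the full analysis chain, and — because the
original microscope images cannot ship with a package — a synthetic plate
generator with exhaustive ground truth that stands in for the instrument, so
every stage is testable at desk scale.

## Pipeline

For every well:

1. **z-collapse.** Brightfield stacks keep their sharpest slice; sharpness
   is the variance of the discrete Laplacian (parameter-free, invariant to
   additive offsets; ties resolve to the lowest index). Fluorescence stacks
   are collapsed by maximum intensity projection so that labelled cells from
   every depth of the embryo remain visible.
2. **Stitching.** The four field tiles are composed along the well axis at
   the nominal offsets implied by the overlap fraction; the stitched width
   is `n·L − (n−1)·round(overlap·L)`. Pixels outside overlaps are copied
   from their source tile unchanged. Overlaps are feather-blended for
   brightfield (no seams to confuse segmentation) and max-blended for
   fluorescence (spot peaks preserved). Optional registration refinement
   adjusts each offset by exhaustive 1-D translation search within ±10 px;
   it is off by default because the alignment plate holds tiles at
   near-nominal offsets.
3. **Segmentation** (brightfield). The reference segmenter normalizes by
   the background level (median intensity — the fish occupies a minority of
   the well), thresholds dark pixels, closes and hole-fills the mask, and
   keeps the largest 8-connected component whose area lies within the fish
   size bounds; no qualifying component means an empty well. Eyes are very
   dark, compact blobs in the anterior half; the yolk (ball plus thin
   caudal extension) is the largest dark region after excluding eyes; the
   tail terminus is the last stretch of the body axis, required to be fully
   inside the image. The segmenter is pluggable: any function with the same
   contract (e.g. a learned model, or the generator-truth oracle used in the
   tests) can replace it, and everything downstream is unchanged.
4. **Region partition.** Each fish pixel takes the region of its projection
   onto the body axis. The trunk/tail boundary sits at the caudal tip of the
   yolk extension — the anatomical definition of where the caudal
   haematopoietic tissue begins. The head/trunk boundary is the posterior
   eye edge plus 5% of body length; the eye is the only reliably detected
   anterior landmark, so this is a stated convention rather than an
   anatomical fact. With landmarks missing, boundaries fall back to fixed
   fractions (0.25, 0.55) of the axis length.
5. **Orientation QC.** A well is analyzable iff the embryo shows exactly one
   eye and exactly one tail (on-side, fully in view) and the fish and tail
   areas exceed minima that catch partially imaged embryos. Checks run in a
   fixed order (empty well, eye count, tail count, fish area, tail area) and
   the first failure is the recorded reason. All wells are exported with
   their QC status; filtering happens at summary time.
6. **Granule detection** (per fluorescence channel), in this fixed order:
   Gaussian smoothing → background subtraction → threshold → 8-connected
   components → area constraints → containment. Background subtraction is a
   grayscale morphological opening with a disc (rolling-ball equivalent):
   the disc is larger than any granule but much smaller than the haze, so
   granules survive subtraction and the haze does not. The default threshold
   is `median(residual) + k·MAD(residual)` with `k = 3.5` and a small
   absolute floor; the median term matters because the opening is a lower
   envelope, giving the residual a positive offset, and the floor guards the
   noise-free/quantization limit. Containment is by centroid: a granule
   counts iff its centroid pixel lies in the fish mask (robust to granules
   touching the outline). Intensity metrics are computed on the original,
   unprocessed image so they do not depend on detection parameters.
7. **Statistics.** Per-condition summaries are mean ± sample (n−1) s.d. over
   QC-included wells, compared by unpaired two-tailed pooled-variance
   (Student) t-tests with `n1 + n2 − 2` degrees of freedom; Welch's form is
   available behind `var_equal = FALSE`. p values are per comparison, with
   no multiplicity correction, matching how such screens are conventionally
   reported.

## The synthetic plate generator

The generator emulates what the analysis must cope with, not what an embryo
looks like. Per well it renders, on a seamless canvas later cropped into
overlapping tiles:

* a tapered-capsule body, darker than the transmitted-light background
  (70% of it), with eyes (15%) and yolk (45%) darkest and a slightly
  brighter thin fin margin (93%); the posterior silhouette stays deep (the
  larval fin fold) before tapering at the tip;
* presentations: `lateral_left`/`lateral_right` (one eye), `dorsal` (two
  eyes), `partial` (tail beyond the image edge), `absent` (background
  only); orientation jitter is uniform within ±4° (the physical alignment
  plate constrains it well below the ±10° the layout permits);
* brightfield defocus: each z-slice is blurred with kernel width
  proportional to `|z − z_focus|` (≈0.6% of tile height per plane),
  implemented as a three-pass box blur whose cost is independent of the
  kernel size;
* fluorescence: a camera offset, a smooth autofluorescence haze over the
  head and yolk footprints, and Gaussian-profile spots. Dim spots peak at
  3 local-background standard deviations above the haze and bright spots at
  10 — reproducing the thresholding dilemma. Each spot's intensity peaks at
  its own z-plane (uniform over the stack) and decays across planes, so no
  single slice holds all the signal and the maximum projection is genuinely
  required;
* noise: shot noise with variance equal to the signal (the Gaussian limit
  of photon counting, accurate at the simulated intensities) plus additive
  read noise (s.d. 12 counts at 16 bits), drawn independently per tile.

Spot placement is rejection sampling inside the true region with a margin of
5.5 spot radii between centres (so spots stay resolvable by the detector in
the noise-free limit) and 2% of body length from region boundaries (so a
small landmark-detection error cannot flip a spot's true region). A
saturated region truncates the drawn count; the ground truth is always the
placed set, so truth tables are self-consistent by construction. The default
screening plate draws tail counts from Poisson(mean 30), a few bright trunk
spots, a couple of bright off-fish objects for the containment rule to
discard, and ~5% misoriented wells (90/96 lateral-left, 1 lateral-right,
2 dorsal, 2 partial, 1 absent).

What the generator does **not** emulate: real optics (only z-dependent
blur), anatomy beyond eyes/yolk/fin, pigment, motion, true photon
statistics, or the variability of real embryos. Passing tests therefore
demonstrate the *mechanics* of the pipeline — geometry, operator chains,
bookkeeping, statistical plumbing — not segmentation accuracy on real
micrographs, which in the original platform is carried by a trained
convolutional network behind the same segmenter contract.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `overlap_fraction` | 0.15 | — | nominal along-well field overlap; the acquisition's "150% coverage" has no published mapping to a fraction, so it is free |
| `z_step` | 50.6 | µm | inter-plane distance of the acquisition |
| `tile_shape` | 512 × 696 | px | desk-scale stand-in preserving the 4-field stitched-strip aspect |
| `pixel_size` | unset | µm/px | physical calibration is instrument-specific; areas fall back to px² and the unit is recorded |
| smoothing σ | 0.6 × granule radius | px | near-matched filter for the expected spot size (radius ≈ 0.8% of tile height) |
| background radius | 4 × granule radius | px | disc opening removes granules into the background estimate while passing the broad haze |
| threshold k | 3.5 | MADs | tuned on synthetic fixtures: recall of the dim class without tail-region false positives; the vendor's per-assay values are not public |
| min/max granule area | 0.15–60 × πr² | px² | rejects noise specks and merged artefacts |
| QC minima | from geometry | px² | fish/tail minimum areas derived from the expected silhouette at the configured resolution |

All pixel-valued defaults derive from the plate geometry, so the same
configuration logic works at any tile resolution.

## Numerical choices and degenerate inputs

* Components are 8-connected; boundary-pixel region assignment is a direct
  label-map lookup, hence deterministic.
* Best-slice ties break to the lowest z index; `which.max` semantics.
* The body axis is the smoothed column-wise midline of the mask — adequate
  for the near-horizontal embryos an alignment plate produces, and stated
  as a limitation for free-swimming orientations.
* Anterior/posterior disambiguation: the axis end nearer the detected eyes;
  with no eyes, the wider end.
* Empty wells are a valid segmentation outcome (`NULL`), not an error; a
  well whose segmentation *errors* is excluded rather than aborting the
  plate. Missing tiles abort with a per-well report.
* The mean granule area of an empty region is `NA`, never 0.
* Grayscale opening uses van Herk/Gil-Werman sliding extrema (exact,
  verified against brute-force disc morphology in the tests).
* Excluded wells are exported with the exclusion reason and empty metric
  cells; read-after-write of the results CSV is byte-identical.

## Problem sizes used by tests and the acceptance script

Checks that need many wells run at reduced tile resolution with all other
study conditions unchanged (Poisson(30) tail spots, default noise, 5%
misoriented): the end-to-end count-recovery plate (96 wells) and the assay
direction checks use 256 × 348 px tiles; the 20 QC-exactness plates use
128 × 174 px brightfield-only tiles; single-well unit tests exercise other
resolutions including full size. These sizes are this package's choices for
desk-scale reproducibility and are stated here so results can be read in
context.

## Known limitations

* The classical segmenter assumes transmitted-light polarity (fish darker
  than background) and near-horizontal orientation; it is a reference
  implementation of the segmenter contract, not a replacement for a trained
  model on real images.
* Registration refinement searches translations along the stitch axis only.
* Only eyes, yolk sac and the tail terminus are populated among the anatomy
  labels; heart, spine, bladder and otic vesicle are reserved.
* Counts of touching granules merge; there is no watershed splitting, by
  design of the operator chain.
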
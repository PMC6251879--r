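---
title: "Counting DNA double-strand-break foci with focimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting DNA double-strand-break foci with focimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Ionising radiation induces DNA double-strand breaks (DSBs). In fixed cells a
DSB is visible as a microscopic *focus* of the phosphorylated histone γH2AX
and of the repair protein 53BP1, detected by immunofluorescence in two
colour channels (green and red respectively). Counting foci per nucleus over
time measures repair; at low doses (tens of mGy) only fractions of a focus
per cell are induced, so thousands of nuclei must be scored — far beyond
what manual counting supports — and unspecific staining artifacts
("background signals") outnumber genuine foci roughly 10- to 20-fold.

`focimetry` implements an automated scoring chain for this setting:

1. **Preprocessing** — nuclei are segmented in the DAPI channel, cropped to
   fixed-size single-cell images (120 px default), the sharpest of the five
   z-planes of each marker stack is selected per cell, and S/G2 or dying
   cells are excluded by a DAPI/γH2AX gate.
2. **Object detection** — candidate signals are seeded at local intensity
   maxima of the red (53BP1) plane and delimited by area growing.
3. **Scoring** — each object receives an object evaluation parameter (OEP)
   combining top-hat contrast, Laplacian-of-Gaussian (LoG) blob response,
   compactness and cross-channel weighting.
4. **Thresholding** — the log-OEP histogram is bimodal (background mode,
   focus mode); the valley is estimated automatically and optionally
   refined by a short rater-in-the-loop adjustment; objects above the
   threshold are foci.
5. **Quality gating and analysis** — samples with weak channel
   co-localization or without a histogram valley are flagged for discard;
   repair efficiency is computed under a linear focus-induction model.

## The object evaluation parameter

For an object with pixel set $\{i\}$ in one channel:

* $I_{TH}$ — mean of the three brightest object pixels in the white top-hat
  transform (image minus its grey-scale opening with a flat disc, 10 px
  diameter by default). The top-hat cancels smooth background and preserves
  peaks narrower than the disc.
* $I_{LC}$ — mean of the three brightest object pixels after the "local
  curvature" transform, a correlation with a fixed 5×5 integer LoG kernel
  (centre coefficient 32). Its response is maximal for blob-like maxima
  near the kernel's own scale; anti-blob (negative) responses are clamped
  to zero, which zeroes the score.
* $C = 1/\sum_i r_i^2 I_i$ — compactness, the inverse intensity-weighted
  second moment about the object's intensity-weighted centroid (a
  moment of inertia with intensity as mass). Distances are measured on the
  raw best-plane image of the channel being scored.
* $I_{nucl}$ — mean nucleus intensity of the channel.

The per-channel score is

$$\mathrm{OEP}_{red/green} = \frac{I_{TH}}{I_{nucl}} \cdot I_{LC} \cdot C,$$

and the two channels are combined with a per-cell weight
$w = I_{SDred}/I_{SDgreen}$ (ratio of in-nucleus intensity standard
deviations, typically 0.9–1.2):

$$\mathrm{OEP} = \mathrm{OEP}_{red}^{\,w} \cdot \mathrm{OEP}_{green}^{\,1/w}.$$

The construction makes the combined score invariant under a positive gain
applied to both channels (the $I_{TH}/I_{nucl}$ ratio and the $I_{LC}\cdot C$
product each cancel the gain), and genuine foci — bright, compact,
co-localized in both channels — outscore channel-independent background
speckles by orders of magnitude.

## Detection parameters

Defaults follow the working values for 8-bit, 120 px crops and are bundled
in `run_config()`:

| parameter | default | meaning |
|---|---|---|
| `local_max_radius_px` | 3 | a seed must exceed every in-mask pixel within this Euclidean radius |
| `min_object_area_px` | 3 | objects smaller than this are discarded |
| `pixel_intensity_factor` | 1.1 | growth floor as a multiple of the nucleus mean |
| `tophat_diameter_px` | 10 | structuring-element diameter, larger than a small focus |
| `crop_size_px` | 120 | single-cell crop side |
| `pearson_min` | 0.4 | minimum mean channel correlation for a valid sample |

The area and intensity floors are deliberately permissive: they bound the
number of background signals (and hence compute) without touching robust
foci.

Numerical conventions, chosen for determinism and stated here because the
operations are sensitive to them:

* Plateaus of equal-valued pixels (common after 8-bit quantization) yield
  one seed, the lexicographically smallest `(row, col)` pixel; a strict
  "greater than all neighbours" rule alone would silently drop them.
* Area growing uses 8-connectivity, includes pixels at exactly half the
  seed intensity, and applies the `1.1 × I_nucl` floor during growth, not
  as a post-hoc filter. Regions from different seeds are disjoint: pixels
  go to the brighter seed, ties to the smaller `(row, col)`.
* Transforms run in floating point; LoG and Sobel use half-sample reflect
  padding, the top-hat clips its disc at image borders. LoG output is not
  clipped at zero; clamping happens only inside the score.
* Single-pixel objects have an undefined compactness (zero moment); their
  `C` is capped at the largest `C` among multi-pixel objects of the same
  cell (fallback constant 10) rather than dropping them, since the
  min-area filter is the intended gatekeeper.
* Ties in the best-plane ratio break to the lowest plane index.
* `log_oep` is base-10; scores at or below zero are floored to the smallest
  positive score in the sample. The inverse representation `1/log10(OEP)`
  is defined only for scores above 1 and used for display; a plain sign
  flip would not sharpen the bimodality, so the reciprocal reading is used.

## Threshold estimation and the rater loop

Three independent estimators locate the transition point on the log-OEP
scale; their mean is the starting threshold, and any estimator that finds
no valley is dropped and logged:

* the valley of a kernel-density estimate. Because the focus population
  occupies the rightmost mode of the score curve, the valley is taken as
  the most pronounced minimum between any earlier mode and the rightmost
  mode above a height floor — background sub-structure (several low-score
  classes) must not capture it;
* the density-equality point of a two-component Gaussian mixture fitted by
  EM. The EM is initialized from the histogram-valley split: with a 10–20:1
  class imbalance a generic initialization tends to split the dominant
  background mode and place the intersection inside the background bulk;
* Otsu's between-class threshold, accepted only if it falls in the bottom
  quarter of the histogram's dip — outside that region Otsu has split a
  mode, not background from foci.

The optional refinement loop mirrors a human validation session: the four
objects scoring closest to the current threshold are shown to a rater
(interactively, or via a programmatic oracle satisfying the same contract);
the threshold moves down by `step × (fraction rated focus − ½) × 2` on the
log scale (foci admit themselves, background pushes the threshold up); the
step starts at a quarter of the distance between the two histogram modes
and decays by 0.8 per iteration with a floor of one histogram bin. The loop
stops when the standard deviation of the last six foci-per-cell values
drops below 5% of their mean (cap 60 iterations), and the final
foci-per-cell value is the mean over the last six thresholds. A 2/2 split
verdict moves nothing but still decays the step, so balanced boundaries
converge.

Foci per cell divides the above-threshold object count by the number of
analyzed (G1-gated) cells, including cells with no objects; gated cells are
used throughout the iteration, consistent with the preprocessing exclusion
step.

## Quality gating

Two empirical checks flag samples whose staining failed:

* the mean per-nucleus Pearson correlation between the two marker channels
  must exceed 0.4 — genuine DSB foci carry both markers, so weak staining
  of either decorrelates the channels;
* the log-OEP histogram must show a pronounced minimum — operationalized as
  a valley at least 10% deeper than the smaller of its two flanking modes
  on the smoothed histogram. Samples with many unspecific signals can
  correlate well yet fail this check.

Failing samples are still written out, but marked for discard.

## Repair-efficiency analysis

Focus induction is linear in dose at 20 foci per cell per gray; 12 mGy
therefore induces 0.24 foci per cell, and a spontaneous level of 0.3 foci
per cell corresponds to 15 mGy (`dose_equivalent()` inverts the model
numerically). Repair efficiency at a time point is the persisting fraction:
`100 × (irradiated − control) / (20 × dose)`, with non-positive differences
flagged rather than clipped.

## The synthetic-data generator

`synth_field()` renders fields with known ground truth so that every stage
can be tested against planted objects. It emulates: nuclei as smooth discs
whose DAPI level and size encode the cell-cycle class (S/G2 at twice the
G1 DNA signal; dying cells undersized, over-bright, with pan-nuclear green
signal, giving the gate something to reject); per-cell focal planes with
integral-preserving defocus of the other four z-planes; foci as bright
compact Gaussian blobs rendered in both channels at co-localized positions;
background speckles as dimmer, slightly broader blobs placed independently
per channel; a shared intranuclear texture (chromatin structure) rendered
identically in both marker channels; a linear background ramp; additive
Gaussian read noise; and 8-bit clipping and quantization applied after
rendering. An optional population of bright diffuse smears (antibody
aggregates; `smear_rate`, off by default) degrades samples on demand for
quality-gate testing.

Default conditions — one field of 1024 × 1360 px holding ~50 nuclei of
radius 30 ± 3 px (the 20×/0.32 µm-per-pixel geometry the 120 px crop size
implies); focus amplitude 150 grey values (±15% log-normal) over a nuclear
baseline of 20; read noise sd 1; 6 speckles per channel and nucleus at
0.3–0.6× the focus amplitude — were fixed once so that the generated data
reproduce the structure the method assumes:

* planted background signals outnumber foci 10–20:1 (12 per nucleus across
  the two channels against 1 focus per cell);
* the pipeline recovers ≥90% of planted foci;
* the log-OEP histogram is bimodal with overlapping tails around the
  valley;
* the mean channel correlation of a healthy sample clears the 0.4 gate —
  carried by the co-localized foci *and* the shared nuclear texture, since
  cells without foci would otherwise contribute no cross-channel
  correlation at all;
* read noise stays below the `1.1 × I_nucl` detection floor. A noise sd
  of several grey values on this baseline would let pure noise
  fluctuations seed thousands of 3-px objects whose compactness
  $C = 1/\sum r^2 I$ is enormous (the moment falls with both extent and
  intensity), swamping the histogram — a regime the floor parameter is
  designed to exclude.

Two width choices deserve explicit notes. Speckles default to 0.9–1.3×
the focus width: narrower speckles would be *more* compact under $C$ and
resonate more strongly with the 5×5 LoG kernel, inverting the intended
contrast (background must be dimmer and less compact than foci for the
bimodality to exist), while much broader speckles tile the nucleus and
bleed into focus regions during area growing. The shared texture is kept
broad (5–10 px) and weak (sd 5) so it correlates the channels without
seeding objects of its own; being rendered identically in both channels,
any texture bump that crossed the detection floor would mimic a dim
co-localized focus.

What the generator does **not** emulate: realistic point-spread functions
and camera noise models (blobs are ideal Gaussians, noise is white),
chromatic shifts between channels, uneven illumination beyond a linear
ramp, dark nucleoli, or clustered damage. Passing tests therefore
demonstrate the pipeline's correctness and calibration on data with the
assumed statistical structure, not its robustness to every real-world
aberration.

## Problem sizes in the test suite

The suite exercises the full chain at the scale the statistics require
while staying quick: oracle-equivalence checks run on ≤ 32 × 32 images over
100 seeds; whole-pipeline recovery uses two synthetic experiments of five
fields (≈ 200–230 analyzed cells) at planted levels of 1 and 0.3 foci per
cell with background speckles at roughly ten times the foci count —
enough cells that the foci-per-cell estimate's sampling error is well below
the tolerances being checked.

## Known limitations

* Detection is 2-D on a single selected plane; cells with many foci at
  high doses are undercounted (a maximum-intensity-projection variant
  would be the natural extension).
* Touching foci closer than the local-maximum radius merge into one
  object; watershed splitting of merged foci is out of scope.
* A focus adjacent to a bright background speckle can grow a joined region
  whose compactness — and hence score — drops; at the default background
  density this affects a small fraction of foci and is partly absorbed by
  the counting trade-off at the valley.
* The G1 gate is a robust stand-in (mode ± 2.5 robust deviations on log
  DAPI, γH2AX mean below median + 2.5 MAD) for a manual two-dimensional
  histogram gate; populations with a dominant non-G1 fraction would need
  manual gating.
* On synthetic benchmarks where ratings are a noisy map of the planted
  blob amplitude, the combined score's rank correlation with the ratings
  sits at or near — but not strictly above — the best single-transform
  scorer. Such an oracle assigns no value to sharpness or co-localization
  beyond the focus/background classification, so per-channel brightness
  scorers reach the rater-noise ceiling by construction, and the small
  fraction of foci that merge with an adjacent bright speckle during area
  growing (collapsing their compactness) costs the combined score a few
  rank inversions that the single-feature scorers do not incur. Human
  raters, who perceive exactly the cues the composite encodes, are the
  setting where its advantage materializes.
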
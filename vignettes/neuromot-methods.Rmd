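---
title: "Methods: quantifying organelle motility, distribution and contacts in neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying organelle motility, distribution and contacts in neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`neuromot` measures how peroxisomes (POs) and mitochondria behave in
cultured hippocampal neurons imaged as two-channel fluorescence recordings:
how far and how fast they move along neurites, how they distribute between
the soma and the proximal neurites, and how often POs sit in contact with
mitochondria.  The package contains both the measurement pipeline and a
synthetic-data generator that plants known ground truth, so every stage can
be validated by parameter recovery rather than by eye.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the simulations do and do not
establish about real data.

# The measurement pipeline

## Neuron segmentation

Neurites are curvilinear, soma-scale structures are blob-like, and both
must be found before any organelle can be measured.

1. **Projection.**  The segmentation input is the sum over channels of each
   channel's temporal maximum projection.  Summation symmetrizes channel
   brightness; the maximum over time turns moving organelles into bright
   trails that reinforce the neurite signal.
2. **Pre-smoothing** (`presmooth_sigma`, default 2 px).  Per-pixel shot
   noise otherwise seeds a percolating web of spurious one-pixel ridges.
   The neurite tube is ~15 px wide, so a 2-px blur costs no structure.
3. **Multi-scale Frangi vesselness** (`frangi_params()`; scales
   {1, 2, 3, 4} px, blobness weight `beta = 0.5`, structureness weight
   `gamma` = half of each scale's maximum sigma-normalized Hessian norm).
   Bright-ridge polarity: response is zero wherever the dominant Hessian
   eigenvalue is non-negative.  A small absolute tolerance
   (`1e-9 * max|image|`) keeps the rounding residue of the discrete
   zero-DC derivative kernels from registering as curvature on flat
   regions — without it the per-image normalization amplifies numerical
   dust to order-one responses.
4. **Non-maximal suppression and hysteresis** (`trace_neurites()`).  The
   response is thinned across the local ridge orientation (quantized to
   4 axes, as in Canny edge detection), then double-thresholded: pixels
   above `high` seed the trace, pixels above `low = high/2` are kept only
   if 8-connected to a seed.  `high` defaults to the Otsu threshold of the
   nonzero thinned strengths computed **on a log10 axis**: the strength
   histogram spans several decades (noise floor ~1e-5, dim cytoplasm tube
   ~1e-2, bright organelle trails ~0.5), and a linear-domain Otsu lands
   between the two bright modes, truncating dim neurite segments, whereas
   the log-domain split falls into the wide empty gap above the noise.
5. **Dilation to an analysis mask.**  The 1-px trace is dilated by
   `round(neurite_width / 2 / pixel_size)` px (8 px at defaults): organelle
   detection needs area, not a skeleton, and the dilation also bridges
   small thinning gaps where a bright organelle blob locally suppresses
   the vesselness.
6. **Soma detection** (`detect_soma()`).  Scale-space difference of
   Gaussians (sigma {10, 15, 20, 25, 30, 40} px, each paired with
   1.6 sigma), maximum over scales, Otsu threshold, then the largest
   8-connected component.  Three numerical choices matter here.  First,
   the filter runs on log-compressed intensities: on a linear scale the
   band-pass response of bright mitochondria trails dominates the dimmer
   soma body and the Otsu threshold can exclude the soma entirely.
   Second, at these scales the DoG of a 10-um soma is an *edge ring*, so
   the largest component is an annulus; filling interior holes recovers
   the disk (measured area ratio 0.93-0.97 on rendered fixtures).  Third,
   organelle-trail response bands — which spread about one filter scale
   beyond the trail — can stay connected to the soma's response, growing
   "tentacles" along neurites; a morphological opening
   (`opening_px = 64`, wider than any trail band, far below the 250-px
   soma diameter) between thresholding and component selection removes
   them.  The filter runs on a 4x block-averaged image — the soma is two
   orders of magnitude larger than a pixel, and filtering at native
   resolution changes the mask by less than the opening does.
7. **Subtraction** (`finalize_masks()`, `soma_margin_px = 12`).  The soma,
   dilated by the margin, is removed from the neurite mask so no pixel
   belongs to both compartments.  The margin is larger than the bright
   halo at the soma boundary plus the trace dilation radius; with a small
   margin the boundary halo survives as a ring of false neurite mask.

On rendered fixtures the final neurite mask covers >= 95% of the planted
centerlines with <= 2% of mask pixels farther than one neurite width from
any centerline, and the soma area is within 10% of the planted disk.

## Organelle detection

Each frame is smoothed with a Gaussian (sigma 1 px for POs, 2 px for the
larger mitochondria), the binarization threshold is computed by Otsu's
method **from the smoothed values at neurite-mask pixels only**, and
8-connected components of at least `min_size = 4` px are reported with
intensity-weighted (sub-pixel) centroids in micrometres.  Choices:

* *Otsu per frame*, so the threshold adapts to bleaching; a frame whose
  histogram is degenerate inherits the previous frame's threshold.
* *min_size = 4 px* removes single-pixel noise at the default SNR.
* *Intensity-weighted centroids*: binary centroids quantize at the pixel
  scale, which would alias into the speed statistics.
* `otsu_threshold()` maximizes between-class variance over a 256-bin
  histogram of the provided values; it is tested for exact equality
  against an exhaustive split-by-split oracle.

## Tracking

Detections in adjacent frames are linked by a globally optimal
nearest-neighbour assignment on centroid distances: the Hungarian method on
a cost matrix padded with per-region "unmatched" alternatives priced at the
gate.  The effective objective is `sum(matched distances) +
max_link_dist * n_unmatched`, which matches everything matchable within the
gate while resolving crossings globally (greedy matching is provably
suboptimal there; tests compare against brute-force enumeration for up to
6 regions per frame).

* `max_link_dist = 1.0` um/frame: the fastest modelled motion is
  0.1 um/s x 5 s = 0.5 um/frame; the gate leaves 2x headroom without
  inviting identity swaps between neighbouring organelles (the simulator
  keeps planted tracks >= 1.5 um apart).
* No gap closing: linking is strictly between adjacent frames; a missed
  detection splits a track.  The cohort statistics therefore filter on
  track duration (below).

## Motility statistics

For a track with per-interval Euclidean displacements `d_i` over a session
of duration `T`:

* steps below `displacement_floor = 0.1` um are zeroed for distance
  accumulation; `total_distance = sum(d_i)`;
* `net_distance` is the straight-line first-to-last distance;
* instantaneous speeds are `d_i / frame_interval`, **unfloored**;
  `max_speed` is their maximum;
* `avg_speed = total_distance / T`.

The displacement floor is the single most consequential free parameter: it
keeps localization jitter (~0.01-0.03 um per frame at the rendered SNR)
from accumulating into fake travelled distance over 96 intervals, while
passing the smallest real modelled step (0.15 um).  The whole-session
definition of `avg_speed` is validated by its own internal consistency: a
track travelling 3.6 um in a 480 s session has an average speed of
0.0075 um/s, and the class framework reproduces exactly that pairing.

Classification by total travelled distance uses half-open intervals:
static [0, 1), very short [1, 5), short [5, 10), long [10, Inf) um.  The
source intervals overlap at their endpoints ("1-5", "5-10"); the half-open
convention is consistent with the explicit ">= 10 um" long-range
definition.

Cohort statistics (class fractions, mean speeds, ECDFs of pooled
instantaneous speeds and of total distances) are computed over tracks
spanning at least `min_samples_frac = 0.9` of the session.  Without a
duration filter, any track fragment produced by a rare missed detection
enters the statistics as a spurious short track and dilutes the class
fractions; 90% keeps tracks that lost a few frames while excluding
fragments.  "Moving" tracks, used for the mean maximal-speed summary, are
those with max instantaneous speed >= 0.05 um/s — above the oscillation
plateau (0.15 um / 5 s = 0.03 um/s), below the run speed.

Directionality is the change in geodesic distance-to-soma (computed within
the neurite mask, 8-connected, diagonal steps cost sqrt(2) px) between a
track's first and last samples: positive = anterograde.  The geodesic
seeds are the neurite pixels within `seed_dilate_px = 14` px of the soma —
just past the subtraction margin — so distances are measured from
approximately the soma boundary; the ~1 um seeded band cancels in
differences and shifts the proximal-region cutoff by ~3% of 30 um.

## Kymographs

`make_kymograph()` samples a polyline at 1-px arc steps; each kymograph
pixel is the *maximum* across a `width`-px segment perpendicular to the
path (maximum rather than mean preserves dim spots).  `kymo_readout()`
converts a hand-drawn line on the kymograph to per-segment velocities
`|dcol| * pixel_size / (drow * frame_interval)` and a total distance.
Automated tracing of kymograph lines is out of scope — lines are drawn by
the analyst; the readout given vertices is what the package provides.

## Distribution and contacts

The fixed-cell pipeline delineates morphology from the cytosol-fill
channel (Otsu + largest component + hole filling), the soma with the DoG
detector, and measures PO counts and areas in the soma and in the
proximal 30 um of the neurites (geodesic cutoff within the neurite mask).
Counts use centroid-in-region membership so a region straddling the
boundary is counted once.  Percent areas are also computed; note that the
normalization of printed percent areas in the source literature is
ambiguous, so no recovery target is built on them.

A PO counts as contacting a mitochondrion iff its binarized region
overlaps or is 8-adjacent to a binarized mitochondrion pixel —
operationally, overlaps the mitochondria mask dilated by
`dilate_px = 1` px (0.08 um).  This is the closest operational reading of
"merging the binarized channels and counting POs free from mitochondria";
there is no distance criterion in the source procedure.  Contacts are
scored in the neurite mask only, on the first frame of a time-lapse.

Group comparisons use a one-tailed unpaired t test, pooled variance by
default (no correction is named in the source; Welch is exposed as an
option), with significance stars at 0.05 / 0.01 / 0.005 / 0.001.
Zero-variance equal-mean degenerate input returns p = 0.5, flagged.

# The synthetic-data generator

The generator defines the study conditions under which recovery is tested.

**Imaging** (`imaging_config()`): 0.08 um/px; 97 frames at 5 s
(96 intervals = 480 s, the "about 8 minutes" session); time-lapse frames
512 x 512 px; fixed-cell and contact fixtures 1024 x 1024 px (matching the
acquisition size of the fixed-cell recordings; the smaller time-lapse
frame keeps 63-neuron cohort simulations tractable and does not change any
per-organelle statistic).

**Geometry** (`make_geometry()`): a 10-um soma disk and five neurites of
45 um leaving the soma radially.  Each neurite is a heading random walk
(8-px steps, heading noise 0.16 rad) confined to its own angular sector
and steered away from the frame border, the soma (2-um clearance after an
initial ramp — the detected soma is subtracted with a margin downstream,
and paths hugging the soma would lose their organelles to it), and all
previously laid points (self-avoidance radius of one neurite width + 5 px,
relaxed by at most 20% after repeated trapping).  In 2-D culture neurites
rarely overlap; keeping them disjoint also removes a tracking confound the
study itself does not quantify.

**Kinetics** (`sample_tracks()`): the source reports class mixtures and
speeds, not a generative model.  Each track draws a class from the preset
mixture, a target total distance uniformly inside the class's interval,
and realizes it as full steps of `run_speed * frame_interval` (0.5 um for
POs at 0.1 um/s; 0.3 um for mitochondria at 0.06 um/s) grouped into
`1 + Poisson(2)` direction-random bouts, plus a remainder of 0.15-um
oscillation steps, with pauses elsewhere.  Consequences, all tested:

* the realized distance (the recorded ground truth) always stays inside
  the planted class's interval;
* no nonzero step is smaller than the oscillation step, so the
  displacement floor (0.1 um) cannot erase genuine motion;
* the long-range interval is closed at 15 um (the source leaves it open);
  with that choice the mixture-times-interval-midpoint cohort means are
  5.3 um (control) and 3.7 um (ACBD5) — within a few percent of the
  printed 5.6 and 3.6 um;
* tracks are confined to one neurite (motion is 1-D along the path,
  rendered in 2-D), matching a kymograph-based analysis;
* organelles occupy disjoint arc-length slots with 1.5-um spacing so
  neighbouring tracks stay resolvable and the linking gate cannot swap
  identities.  Slots are placed by first-fit decreasing with randomized
  leftover gaps.

**Rendering** (`render_timelapse()`): POs are 2-D Gaussians
(sigma 0.15 um, diffraction-like), mitochondria soft-edged capsules
(1.5-3 um long, ~0.4 um wide) oriented along the local path tangent, on a
background of 100 counts with the neurite tube at +60 and the soma at
+150, Poisson photon noise and Gaussian read noise (sigma 10) quantized to
integer counts.  The source states no intensities or SNR; these defaults
were calibrated once so that (a) centroid jitter is below 0.1 px, making
class recovery detection-limited rather than noise-limited, and (b) the
neurite cytoplasm is bright enough for ridge tracing, which is a stated
property of the acquisitions being emulated.  Rendering is bit-identical
for a fixed seed; z-dimension, photobleaching, focus drift and
fission/fusion are not simulated (the last is observed but not quantified
in the source).

**Fixed-cell fixtures** (`render_fixed_neuron()`): plants exact spot
counts (e.g. 174 somatic / 65 proximal-neurite POs for the control preset)
with total footprint areas of 22 / 6 um^2.  Two packing details:

* `min_spot_separation` (0.5 um) is interpreted as clear distance between
  spot *boundaries*.  At centre-to-centre reading, 0.5-um pairs of
  diffraction-limited spots merge under the pipeline's own sigma = 1 px
  smoothing, making exact count recovery impossible for any detector
  without watershed splitting (excluded from scope); the boundary reading
  is the natural packing meaning and makes counts exactly recoverable.
* 174 spots at that separation fill ~49% of the feasible soma area —
  beyond the saturation regime where random sequential placement stalls —
  so somatic spots are drawn from a jittered hexagonal lattice
  (deterministic, guaranteed feasible, blue-noise-like).

Because the spots are sub-resolution, their only well-defined rendered
area is the binarized footprint; the renderer calibrates the per-spot
Gaussian width by a three-step fixed-point iteration so that the footprint
measured by the standard detection operator on a noise-free render equals
the requested total.  Measured areas on noisy fixtures land within ~1% of
the planted 22 um^2.

**Contacts** (`make_contact_fixture()`, `plant_contacts()`): mitochondria
capsules (2-3.5 um) are laid densely along the neurites, alternating short
(1 um) gaps with occasional 3.2-um clearance gaps; each of 200 POs draws a
Bernoulli contact label at the preset fraction (84.6% for the control
preset); contacts sit on a mitochondrion, non-contacts at >= 1 um from any
mitochondrion boundary, all POs >= 0.8 um apart.  The planted fraction (a
binomial realization) is recorded in the ground truth, and the full
detection + adjacency pipeline recovers it to within one or two POs.

# Problem sizes and determinism

Recovery cohorts use 21 neurons x 25 tracks = 525 tracks per preset,
97 frames at 512 x 512 px — about 10 s per neuron for
simulate-render-segment-detect-track on one core.  Fixtures for contact
and fixed-cell recovery are single 1024 x 1024 scenes.  All randomness
flows through explicit integer seeds (neuron `i` of a cohort run at base
seed `s` uses `s * 1000 + i`); there is no hidden global state, and every
render is a pure function of its inputs and seed.

# What passing recovery shows — and what it does not

The simulations establish that the pipeline is *correct*: planted class
mixtures, speeds, distances, counts, areas and contact fractions are
recovered within sampling error through the full
segmentation-detection-tracking-classification chain.  They do not
establish robustness to everything real recordings contain: out-of-focus
light and z-projection artefacts, photobleaching trends, organelle
fission/fusion, crossing or fasciculating neurites, astrocyte background,
or stage drift are all absent from the generator.  Results on real data
therefore depend on acquisition quality in ways these tests cannot bound;
the parameter defaults above (hysteresis thresholds, displacement floor,
link gate) are the knobs to revisit first when they are violated.

# Known limitations

* TIFF metadata is stored in a `metadata.json` sidecar (the installed TIFF
  writer does not persist description/resolution tags).
* Touching organelles are not split (no watershed); the simulator keeps
  planted organelles resolvable instead.
* Kymograph lines are supplied by the analyst, not traced automatically.
* The geodesic zero point sits ~1 um outside the detected soma (the seeded
  band), a deliberate trade for robustness of the soma subtraction margin.
* Percent-area normalization for neurites is reported but not validated
  against an external value (ambiguous source definition).
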
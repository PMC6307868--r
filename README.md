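# neuromot

Quantitative analysis of peroxisome (PO) and mitochondria behaviour in
cultured neurons, from two-channel fluorescence recordings: organelle
**motility** along neurites (time-lapse), PO **distribution** between soma
and proximal neurites (fixed cells), and PO–mitochondria **contact
fractions**. The package is aimed at cell biologists studying organelle
transport and tethering in neurons, and at anyone who needs a fully
testable re-implementation of this style of organelle-tracking pipeline.

Because studies of this kind rarely deposit raw imaging data, `neuromot`
ships a synthetic-data generator that renders ground-truthed neurons —
planted geometry, trajectories, spot counts and contacts — so that every
stage of the measurement chain is validated by parameter recovery.

## The pipeline

For a time-lapse stack with PO and mitochondria channels:

1. **Neurite tracing** — multi-scale Frangi vesselness
   $V = \exp\!\left(-\frac{R_b^2}{2\beta^2}\right)\left(1 - e^{-S^2/2c^2}\right)$
   of the σ-normalized Hessian (eigenvalues $|\lambda_1|\le|\lambda_2|$,
   blobness $R_b = \lambda_1/\lambda_2$, structureness
   $S = \sqrt{\lambda_1^2+\lambda_2^2}$; $V=0$ where $\lambda_2 \ge 0$),
   maximum over scales σ ∈ {1,2,3,4} px, followed by non-maximal
   suppression across the ridge and double-threshold hysteresis — a ridge
   analogue of Canny edge detection. The soma is a scale-space
   difference-of-Gaussian blob (largest detected object) and is subtracted
   from the neurite mask.
2. **Organelle detection** — per-frame Gaussian smoothing (σ = 1 px for
   POs, 2 px for mitochondria), Otsu threshold computed from the smoothed
   values *inside the neurite mask only*, 8-connected component labelling,
   intensity-weighted centroids.
3. **Tracking** — globally optimal nearest-neighbour assignment of
   centroids between adjacent frames (Hungarian method with a 1 µm/frame
   gate), minimizing total matched distance.
4. **Motility statistics** — per track: maximum and average speed (µm/s),
   total and net travelled distance (µm), with a 0.1 µm displacement floor
   against localization jitter; classification by total distance into
   static (< 1 µm), very short (1–5 µm), short (5–10 µm) and long-range
   (≥ 10 µm) movement; anterograde/retrograde directionality from the
   geodesic distance to the soma; kymographs with line readout.
5. **Distribution & contacts** — PO counts/areas in the soma versus the
   proximal 30 µm of the neurites; a PO is in contact with a mitochondrion
   iff its binarized region overlaps or is 8-adjacent to the binarized
   mitochondria mask; one-tailed unpaired *t* tests for group comparisons.

## Worked example

Simulate one control neuron, render it, and run the full measurement
pipeline:

```r
library(neuromot)

cfg    <- imaging_config()           # 0.08 um/px, 97 frames every 5 s
geom   <- make_geometry(cfg, seed = 1)
tracks <- sample_tracks(geom, motility_preset("control-PO"), 25, cfg, seed = 2)
stack  <- render_timelapse(geom, po_tracks = tracks, config = cfg, seed = 3)
res    <- run_motility(stack)
res$cohorts$PO
```

```
imaging_config: 97 frames of 512x512 px, 0.08 um/px, 5 s interval (480 s session)
neuron_geometry: soma r=10 um at (256,256), 5 neurite(s), lengths 45.4/... um
ground_truth_tracks: 25 PO track(s); classes static=0, very_short=12, short=12, long=1
cohort_summary: 25 tracks | static 0.0% very_short 48.0% short 48.0% long 4.0% |
                avg 0.01156 um/s, max 0.101 um/s, dist 5.55 um
```

Reading the output: all 25 planted organelles were re-found as full-length
tracks; the measured class mixture equals the planted one for this neuron
(12/12/1 very-short/short/long); the cohort mean of the per-track maximum
instantaneous speeds (0.101 µm/s) recovers the 0.1 µm/s run speed the
simulator planted, and the mean travelled distance (5.55 µm) matches the
planted mean (5.61 µm) to ~1%. At cohort scale (≥ 500 tracks over 21
neurons, `run_simulated_cohort()`), the recovered class fractions land
within binomial sampling error of the preset mixture — 1/59/30/10 % for
control POs, 3/81/14/2 % under ACBD5 overexpression, 75/5/5/15 % for
mitochondria.

Fixed-cell and contact analyses follow the same pattern:

```r
fx  <- render_fixed_neuron(fixed_neuron_spec("fixed-control"),
                           imaging_config(n_frames = 2,
                                          frame_shape = c(1024L, 1024L)),
                           seed = 7)
analyze_fixed_neuron(fx)$summary
#              region po_count po_area_um2 region_area_um2 percent_area
# 1              soma      174     21.9456        296.0384    7.4131...
# 2 proximal_neurites       65      5.9712        190.6240    3.1324...

cs <- analyze_contacts(make_contact_fixture(seed = 5))
cs$contact_fraction        # 0.805 measured vs 0.81 planted (n = 200)
```

A thin command-line wrapper is installed at `inst/scripts/neuromot`
(subcommands `simulate`, `motility`, `distribution`, `contacts`); pipeline
parameters live in a validated YAML config (`default_run_config()`,
`load_run_config()`).

## Testing

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "neuromot",
                               load_package = "installed")'
```

The suite covers exact oracles (Otsu versus exhaustive histogram search,
assignment versus brute-force enumeration), property-style invariants
(hysteresis set membership, distance identities, ECDF monotonicity), and
end-to-end parameter recovery on simulated cohorts. The recovery tests
take the bulk of the runtime (about 10 minutes on one core).

## Method documentation

`vignettes/neuromot-methods.Rmd` documents the models and their
assumptions, every tunable parameter with units and default, the numerical
choices (threshold domains, margins, tolerances, tie-breaks), what the
synthetic generator does and does not emulate, and known limitations.
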
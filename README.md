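# fluortrack

Tracking and behavior classification for multichannel fluorescence
time-lapse microscopy of tissue.

## What problem this solves

When a tissue is mechanically stimulated — the motivating system is
articular cartilage subjected to a rapid local impact, where overloading is
known to initiate osteoarthritis — thousands of resident cells respond over
milliseconds to hours, and the response depends on each cell's position
relative to the stimulus. Three fluorescent reporters read out the relevant
physiology per cell: nuclear membrane permeability (blue, a proxy for cell
death), cytosolic calcium (green), and mitochondrial membrane potential
(red). Turning a multi-hour, three-channel image stack of ~1000 moving,
blinking cells into a spatial map of *behaviors* requires: robust tracking
through fluorescence fluctuation, clean per-cell intensity traces, feature
extraction (calcium transients, permeability steps), and classification of
every trace into a recognizable behavior category.

`fluortrack` is an R package for that pipeline, aimed at imaging labs doing
tissue-scale mechanobiology or any system where cell state can be read from
fluorescence over time. It includes a synthetic-scene generator that
renders ground-truth image stacks, so the whole pipeline is testable
without any experimental data.

## The method

- **Tracking**: cells are located on the summed-channel image by band-pass
  filtering + intensity-weighted centroid refinement (Crocker–Grier style),
  linked by nearest-neighbor assignment with displacement cap
  `max_link_displacement` and a `max_gap_frames` memory. Internal gaps are
  filled by linear interpolation when the bracketing detections are within
  `max_gap_displacement` (about one cell diameter); after the tissue
  relaxes, tracks are extended at their last position (`extend_static`).
- **Traces**: per frame and channel, an 8×8 tiled grid background is
  subtracted (mean of the 20 lowest pixels per region — 4096 pixels per
  region on a 512×512 frame), then the 3×3 neighborhood of the rounded
  centroid is averaged; traces are smoothed with a centered 20-frame moving
  average.
- **Features**: transient peaks are local maxima with topographic
  prominence ≥ 3 a.u. and half-prominence-width/prominence ≤ 10; intensity
  steps come from penalized piecewise-linear segmentation with a drift
  filter on the bracketing fits.
- **Classification**: a fixed decision tree assigns one of twelve behavior
  categories (A–L, see `?behavior_categories`) from the fingerprint —
  e.g. blue max > 7 before frame 7 ⇒ "permeability starts elevated" (A);
  > 3 blue changepoints ⇒ "multiple permeability levels" (L);
  mean(red − blue) > 20 ⇒ "polarized mitochondria despite permeability
  increase" (E); green peaks before vs after the first blue changepoint
  separate H from G; red mean after frame 50 below 6 separates K from J.
- **Mapping**: labels are binned by cell position into per-category count
  grids for heat maps.

See the methods vignette (`vignettes/behavior-classification.Rmd`) for the
model, parameter meanings and numerical choices.

## Worked example

Simulate a 200-cell impacted field, run the full pipeline, and score the
labels against the generator's ground truth:

```r
library(fluortrack)

cfg <- pipeline_config(
  scenario = list(n_cells = 200, frame_count = 300, field_size = 512,
                  impact_center = c(256, 256)),
  render = list(background_level = 5, camera_noise_sd = 1),
  seed = 1)
paths <- run_pipeline(cfg, "run1")

table(read.csv(paths$labels)$category)
#>   A   B   C   F   G   H   I   J   K
#>  15   5  30   2   3   1  21 120   5

read.csv(paths$report)
#>    Category Accuracy Total.Cells
#> 1         A        1          15
#> 2         B        1           5
#> 3         C        1          30
#> 4         D       NA           0
#> 5         E       NA           0
#> 6         F        1           2
#> 7         G        1           3
#> 8         H        1           1
#> 9         I        1          21
#> 10        J        1         120
#> 11        K        1           3
#> 12        L       NA           0
#> 13    Total        1         200
```

Reading the output: most cells are normal (J), cell-death behaviors (here
A, C dominate among the rest) sit near the impact center, and every
ground-truth cell the tracker recovered was classified into its generating
category (`Accuracy` is true positives over ground-truth count per
category; `NA` marks categories absent from this simulation, reported as
undefined rather than zero). `run1/` also holds the rendered TIFF stack,
tracks, traces, fingerprints, per-category map CSVs and a `manifest.json`
with md5 hashes; rerunning with the same seed reproduces the CSVs byte for
byte.

A thin command-line wrapper with `simulate` / `track` / `extract` /
`features` / `classify` / `map` / `benchmark` / `run` subcommands is
installed at `inst/cli/fluortrack.R`.

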
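# calpipe

Automated detection of spontaneous calcium signaling events in two-channel
time-lapse microscopy of *Drosophila* lymph gland prohemocytes.

Prohemocytes — the stem-cell-like blood progenitors of the larval lymph
gland — show spontaneous calcium transients that help regulate their
maintenance and differentiation.  Recording them *ex vivo* with a red
nuclear marker (mCherry) plus a green intensiometric calcium biosensor
(jGCaMP8s) driven in the same cells, and then selecting active regions by
hand, is labour-intensive and biased toward clearly spiking, bright cells.
`calpipe` implements an unbiased, fully automated alternative for users of
such recordings: every cell that stays trackable for the whole movie gets a
fluorescence trace, and events are called by a fixed, documented rule.

## The pipeline

For paired red/green stacks (T frames of H × W pixels, frame interval
Δt, default 5 s):

1. **Photobleaching correction** — the per-frame spatial mean is fit to
   I(t) = A·e^(−t/τ) + C and each frame is rescaled by
   (A + C)/(A·e^(−t/τ) + C), per channel.
2. **Block averaging** — every 5 consecutive red frames are averaged to
   raise nuclear signal-to-noise before detection.
3. **Nucleus detection and tracking** — local maxima of the
   scale-normalized Laplacian-of-Gaussian response (scale σ = r/√2 for
   nucleus radius r) are linked across blocks by greedy disk
   intersection-over-union matching; only tracks spanning every block are
   kept, and per-block label masks are rendered from them.
4. **Trace extraction** — each cell's trace is the mean bleach-corrected
   green intensity over its mask pixels at every raw frame, minus the
   background estimated from a recording of cells with no green
   fluorophore.
5. **Event calling** — a per-cell baseline B is estimated by iteratively
   fitting a cubic polynomial and clipping samples above the fit plus a
   noise margin; frames with (F − B)/B > 0.25 are marked, and maximal
   marked runs become events with duration (end − start + 1)·Δt.
6. **Statistics** — per-cell basal intensity (event frames excluded), the
   standard deviation of log basal intensities (a scale-free measure of
   expression heterogeneity), event-duration survival fractions, and a
   control-based false-discovery-rate estimate:

   FDR = (control events / control cells) / (signal events / signal cells),

   where the control sample expresses an inert fluorophore (EGFP) in place
   of the biosensor, so every event detected in it is an imaging artifact.

A ground-truthed synthetic movie generator (`simulate_movie()`) emulates
the recordings — drifting Gaussian-blob nuclei, log-normal per-cell
expression driven by a shared driver-activity level, sparse boxcar calcium
transients (absent in control mode), exponential photobleaching, additive
background and pixel noise — and validates every stage of the pipeline.

## Worked example

```r
library(calpipe)

cfg <- sim_config(n_cells = 30, seed = 42)   # 15 min at 5 s, 160x160 px
sim <- simulate_movie(cfg)
sim$movie
#> two_channel_movie: 160 x 160 px, 180 frames at 5 s (15.0 min)
sim$truth
#> ground_truth: 30 cells, 180 frames, 106 true events

res <- run_pipeline(run_config(sim = cfg))
res$summary$n_cells_tracked                     # 30
res$summary$n_events                            # 114
round(res$summary$mean_events_per_cell, 2)      # 3.8
round(res$summary$duration$fraction_at_least, 3)
#> ge_20s ge_60s
#>  0.333  0.026
round(res$summary$log_sd_basal, 3)              # 1.485
head(res$events, 3)
#>   cell_id start_frame end_frame duration_s peak_rel_amplitude
#> 1       1           1         1          5          0.5781703
#> 2       1          19        19          5          0.3222188
#> 3       1         150       152         15          0.9714119
```

30 of 30 simulated cells stay trackable (the default drift is mild), and
the caller finds 3.8 events per cell.  A third of detected events last at
least 20 s; about 30% last a single frame (5 s).  The log-scale standard
deviation of basal intensities, 1.49 here, reflects the wide log-normal
expression heterogeneity the generator imposes (`expression_log_sd = 1.7`,
shrunk slightly by measurement floors at this small sample size).

With real data, replace the `sim` input by TIFF paths:

```r
run_pipeline(run_config(red_path = "red.tif", green_path = "green.tif",
                        background_path = "background_green.tif",
                        frame_interval_s = 5, out_dir = "out"))
```

A command-line interface wrapping the same functions is installed at
`system.file("scripts", "calpipe", package = "calpipe")` with subcommands
`simulate`, `preprocess`, `track`, `traces`, `events`, `stats` and `run`.

## Limitations

The simulator is two-dimensional: it models in-plane tissue drift but not
the z-axis drift and focus loss that dominate false positives in real
recordings, so simulated control movies yield fewer artifact events than
real EGFP controls.  Detection thresholds (LoG quality, relative event
threshold) are tuned on the simulator; real data may need adjustment.  See
the methods vignette (`vignettes/calcium-event-detection.Rmd`) for the
full model description, parameter rationale, and known limitations.
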
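---
title: "Methods: automated calcium event detection in two-channel time-lapse movies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated calcium event detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and experimental picture

`calpipe` analyzes paired single-channel time-lapse stacks of *Drosophila*
lymph gland prohemocytes: a red channel carrying a nuclear marker
(mCherry) used only to find and follow cells, and a green channel carrying
either an intensiometric calcium biosensor (jGCaMP8s; fluorescence rises
with intracellular calcium) or an inert fluorophore (EGFP) used as a
negative control.  Both transgenes are driven in the same cells by one
driver (Tep4-Gal4), whose activity varies strongly from cell to cell, so
per-cell brightness spans orders of magnitude in both channels and the two
channels' brightness is correlated.

The biosensor is intensiometric, not ratiometric: a bright cell is not
necessarily a high-calcium cell.  The pipeline therefore never compares
absolute intensities between cells; events are excursions *relative to
each cell's own baseline*, and cross-cell statistics use log-transformed
values, whose dispersion is scale free.

# Stage-by-stage model

## Photobleaching correction

Fluorophores bleach during 15 minutes of repeated excitation.  We model
the frame-mean intensity as $I(t) = A e^{-t/\tau} + C$ and fit $(A, \tau,
C)$ by Levenberg–Marquardt least squares on the spatial mean trace — a
stack-level fit, not per-pixel, which is robust at these image sizes and
matches how stack bleach correction is usually applied.  Frame $t$ is then
*multiplied* by $(A + C) / (A e^{-t\Delta t/\tau} + C)$.  The
multiplicative form preserves each trace's relative excursion
$(F - B)/B$, which the event caller thresholds; a subtractive correction
would distort it.  Assumptions: bleaching is global and exponential, and
the background bleaches with the same envelope (true of autofluorescence,
approximately true of stray light; the simulator renders it that way).
Both channels are corrected independently by default, with per-channel
opt-outs (`correct_red`, `correct_green`), since the original protocol
does not state which channels were corrected.

Fits are started from a small grid of initial values because the model is
nearly collinear when the recording is short relative to $\tau$.  A trace
with no measurable decay yields a flagged identity fit whose correction is
a no-op, so event-free flat inputs pass through unchanged.

## Block averaging and nucleus tracking

Every 5 consecutive red frames are averaged (remainder frames dropped, so
output length is deterministic), trading 25 s of temporal resolution for
$\sqrt5$-fold noise reduction in the channel used only for localization.
Nuclei — bright, round, non-overlapping — are detected per averaged frame
as local maxima of the scale-normalized Laplacian-of-Gaussian response at
the single scale $\sigma = r/\sqrt2$ for nucleus radius $r$ (default 5
px); for a Gaussian blob of matched size the peak response is about half
the blob's amplitude, which makes the quality threshold interpretable in
intensity units.  Sub-pixel centers come from per-axis quadratic
interpolation of the response; duplicate maxima within one radius are
suppressed deterministically (higher quality wins; ties to smaller row,
then column).

Linking between consecutive averaged frames is greedy
intersection-over-union matching of the detection disks (analytic
circle-overlap area), accepting IoU ≥ 0.1 by default — an "overlap
tracker" in the TrackMate sense, re-specified exactly because the original
tool's parameters are not reported.  No gap closing, splitting or merging:
a cell that disappears for one block terminates its track.  Only tracks
spanning *every* block are analyzed further, mirroring the requirement
that cells remain in the focal plane for the whole recording.  Label masks
are rendered per block as filled disks at the tracked centers (nearer
center wins contested pixels; ties to the lower id), so masks follow
drifting cells and reduce to a static mask when drift is zero.

One consequence worth knowing: completeness filtering plus a quality
threshold silently drops the dimmest cells.  In simulations with the
default expression spread, roughly 5% of cells are lost this way, and
because the loss is one-sided it *shrinks* the measured log-scale spread
of basal intensities by a few percent relative to the generator's
parameter.  The same selection operates in the real experiment.

## Traces, background, baseline, events

Traces are sampled at raw-frame resolution (each raw frame uses its
block's mask): event durations must be measurable at the 5 s interval, not
at the 25 s block interval.  The trace is the plain mean over mask pixels;
since calcium reported by the biosensor is fairly uniform within a cell at
this resolution, the nuclear-footprint mean approximates the whole-cell
mean.

Background (stray light plus autofluorescence) is measured from a separate
recording of cells carrying the nuclear marker but *no* green fluorophore,
as the per-frame spatial mean of its bleach-corrected green channel, and
subtracted per frame (additively — it is additive light).  Corrected
traces are floored at $10^{-6}$ of each trace's maximum so that
baseline-relative ratios stay defined for cells whose signal is
indistinguishable from background.

The baseline is an iterative asymmetric polynomial fit: fit a cubic to the
trace, clip samples lying above the fit *plus a noise margin* (the
standard deviation of the below-fit residuals), refit, and stop when the
coefficient vector changes by less than $10^{-3}$ relative (or after 100
iterations, returning the last iterate with a flag).  The margin matters:
clipping at the bare fit lets the fit's own dips drag clean samples down
on each iteration, settling several percent below the quiescent level on
a flat trace with one transient, and far below it on noise-dominated
traces — which converts dim control cells into false-positive factories.
With the margin, a flat trace with a 60% boxcar transient recovers its
baseline to well within 2%, and pure-noise traces mark only ~1–2% of
frames at the default threshold.  This is the package's design choice in
the spirit of modified-polynomial (ModPoly/IModPoly-style) baseline
correction.

Events are maximal runs of frames with $(F - B)/B > 0.25$ (strictly
greater), runs separated by at most `merge_gap` unmarked frames merged
(gap frames count toward the duration), and merged runs shorter than
`min_frames` discarded.  Defaults: threshold 0.25, `min_frames = 1` (the
experiment reports single-frame, 5 s events, so they must be
representable), `merge_gap = 0`.  The threshold, like the LoG quality
threshold, is not reported in the original study; both defaults here are
tuned on the simulator and exposed as parameters.  Durations are exact
multiples of the frame interval by construction; events truncated by the
movie boundary count at their observed duration (no censoring
correction).

## Statistics

* **Basal intensity**: per-cell mean of the corrected trace over frames
  outside detected events.
* **Expression heterogeneity**: sample standard deviation (n−1) of
  *natural-log* basal intensities.  The log base is recorded; comparisons
  and percent differences are base-invariant.  The companion
  `percent_difference(sigma_signal, sigma_control)` reproduces the
  published comparison (1.792 vs 1.688 → 6% to the nearest percent).
* **Durations**: survival fractions (fraction of events lasting at least
  each threshold; "at least 20 s" means ≥ 20 s, "a minute or more" means
  ≥ 60 s) plus the single-frame fraction.  The plotting helper excludes
  durations above 125 s from the histogram only; statistics always use
  all events.
* **False-discovery rate**: every event detected in the inert-fluorophore
  control is an artifact, so
  $\widehat{FDR} = (E_c/N_c)\,/\,(E_s/N_s)$ — the per-cell event-rate
  ratio, which normalizes the unequal cell counts (250 vs 245 in the
  published experiment).  The raw count ratio $E_c/E_s$ is reported
  alongside because the published arithmetic is not shown; on the
  published counts both land just under 5%.

# The synthetic movie generator

`simulate_movie()` renders the study conditions so every stage can be
validated against known truth:

* **Geometry**: `n_cells` nuclei placed uniformly with minimum center
  separation of 3 nuclear radii (a cell diameter — the cytoplasmic green
  footprint extends ~1.5 nuclear radii), margins keeping footprints in
  frame.  Default 30 cells in 160 × 160 px; the acceptance runs use
  250/245 cells in 512 × 512 px at the same density.
* **Motion**: independent per-cell Gaussian random walks
  (`drift_step_px = 0.15` px/frame, reflecting at the margins) emulate
  the slow in-plane tissue drift tolerated in the original recordings.
* **Expression**: a shared per-cell driver activity
  $\log L \sim \mathcal N(6.5, 1.7^2)$ scales both channels, with
  independent per-channel log-normal jitter (sd 0.2).  The log-sd 1.7
  matches the published basal-intensity spread; the mean puts the median
  nucleus at several hundred counts on the 16-bit scale, and the
  correlation between channels reflects shared driver dosage — which is
  also what lets tracking (red) exclude cells too dim to quantify
  (green).
* **Events** (signal mode only): per-cell Poisson counts with mean 3.3
  per movie (the published 812 events among 245 cells), starts uniform,
  durations geometric over frames with stop probability 0.3 per frame —
  matching the monotone-decreasing published histogram and putting a
  third of events at ≥ 4 frames (20 s) — and per-event relative
  amplitudes log-normal with median 1.0 (sd of logs 0.5).  The biosensor's
  kinetics are an order of magnitude faster than the 5 s frame interval,
  so transients are rendered as boxcars with no rise/decay shaping.
  Events of one cell are separated by at least one quiescent frame, as
  distinct physiological transients return to baseline between peaks.
  The published study reports no amplitude scale, so the amplitude
  defaults are the package's own and are exposed in the configuration.
* **Optics**: nuclei are isotropic Gaussians (sd $r/\sqrt2$, truncated at
  3 radii); the green cellular footprint is 1.5× wider.  Both channels
  decay as $e^{-t/\tau}$ (default τ = 900 s, a moderate bleach losing
  ~63% over the 15-minute movie) applied to cellular signal *and*
  background, then constant background (100) and additive Gaussian pixel
  noise (sd 2) are applied and intensities clipped to the unsigned 16-bit
  range.  Gaussian rather than Poisson noise is a deliberate
  simplification; `noise_sd` can approximate shot-noise regimes.
* **Control mode** replaces the biosensor with an inert fluorophore:
  identical rendering, zero true events.  `simulate_background_movie()`
  renders the background-estimation genotype: red nuclei, green channel
  with background, bleaching and noise only.

Identical configuration and seed give bit-identical stacks and truth
tables.

What the generator does **not** emulate: z-axis drift and focus loss
(named in the original study as the dominant false-positive source),
optical PSF structure, sensor photophysics (dark states, saturation),
Poisson statistics, and spectral bleed-through.  Simulated control movies
therefore yield far fewer artifact events than real EGFP controls (the
synthetic FDR lands near 0% rather than near the published ~5% bound),
and passing synthetic tests bounds algorithmic error, not real-data
performance under focus instability.

# Numerical choices and degenerate inputs

* Coordinates are 0-based `(row, col)` with pixel centers at integer
  positions; frame indices are 0-based in all tables; times in seconds.
* All tie-breaks are deterministic and documented (detection NMS: quality,
  then row, then column; linking: IoU, then lower track id; mask pixels:
  nearer center, then lower id; event matching: overlap length, then
  earlier start).
* Blank or constant frames yield empty detection lists, not errors; a
  constant stack yields an identity bleach fit; an all-constant trace is
  its own baseline.
* A label with no pixels in some block, a non-positive value passed to
  `log_sd()`, an all-event trace in `basal_intensity()`, and an FDR with
  zero biosensor events raise informative errors rather than silent NAs.
* `estimate_baseline()` floors its output at $10^{-6}$ of the trace
  maximum, making a non-positive baseline in `detect_events()` a genuine
  internal-invariant violation.

# Validation design and problem sizes

The test suite builds every fixture in code.  Unit tests validate each
operation against independent oracles: a grid-search + Nelder–Mead
exponential fit, a brute-force run-length scanner checked over *all*
marked/unmarked patterns up to length 12 for a grid of
(`min_frames`, `merge_gap`), Monte-Carlo point sampling for the disk-IoU
formula, and analytic renderings for detection localization.  End-to-end
checks run the full pipeline on simulated movies: a drift-free noiseless
20-cell movie must be tracked completely with sub-pixel accuracy, and the
headline validation pairs a 250-cell control-mode movie with a 245-cell
signal-mode movie (512 × 512 px, 180 frames — the scale of the published
experiment) to verify the control-based FDR bound, expression-spread
recovery (measured on truth-footprint traces of all simulated cells, to
separate measurement fidelity from tracking selection), and matched-event
recall/precision for true events with relative amplitude at least twice
the detection threshold and at least two frames long.  These sizes keep
the full suite in the tens of minutes on one CPU while exercising the
pipeline at experimental scale.

# Known limitations

* Single z-plane; no registration or gap-closing, so transient focus loss
  removes a cell from analysis entirely.
* Stack-level bleach model; per-pixel bleach heterogeneity and
  flat-field/illumination structure are out of scope.
* Touching nuclei are resolved by NMS and nearest-center mask partition,
  not segmentation; heavily overlapping nuclei would be mis-assigned.
* The event caller reports what crosses the threshold: sub-threshold
  events are invisible, and amplitudes of clipped (sensor-saturated)
  transients are compressed.
* Detection defaults are simulator-tuned; on real data the LoG quality
  threshold in particular depends on acquisition gain and should be
  checked against a control recording.
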
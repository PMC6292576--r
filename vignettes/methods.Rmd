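---
title: "Methods: from embryo video to phenome traits, cardiac models and end points"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from embryo video to phenome traits, cardiac models and end points}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(embryovision)
```

# Data model

An experiment is a roster of embryos recorded on a repeating schedule:
bursts of `frames_per_sequence` frames at `frame_rate` fps, one burst
every `repeat_interval` minutes, `n_timepoints` times. The timepoint
count is always declared explicitly in the configuration rather than
derived from a duration, because "hourly for 24 h" is genuinely
ambiguous (24 or 25 recordings; both conventions occur in real
designs). Frames are 16-bit grayscale, dark-field: a bright embryo
inside a bright egg-capsule ring on a dark background. Pixel
coordinates are 0-based, row-major, origin top-left; geometric
quantities are reported in pixels and, when a scale (µm/px) is set, in
µm (areas via scale²).

Failed or missing frames are carried as NaN rows, never dropped, so
the time axes of all variables stay aligned; partial sequences are the
norm in real acquisitions, not an error.

Results are stored per embryo as a `phenome_dataset`: a directory with
JSON metadata and one full-precision CSV per group (`traits`,
`cardiac`, `endpoints`, `spectra_L<level>`). Floats are serialized
with 17 significant digits, which round-trips IEEE doubles exactly, so
`read_dataset(write_dataset(d))` is bit-identical and re-written files
are byte-stable; the NA/NaN distinction (absent vs masked) survives
the round trip. A `format_version` stamp makes incompatible layouts
fail with a migration error instead of being misread.

# Egg location and segmentation

The egg capsule is static while the embryo moves inside it, so the
capsule region is visible both in a max-intensity projection (bright
ring) and in a temporal variance map (moving embryo interior).
`locate_egg()` normalizes both maps to [0, 1], takes their pixelwise
maximum, thresholds a quarter of the way up from the background median
(dark-field backgrounds sit at the low end; an Otsu threshold is
deliberately *not* used here because it splits the two foreground
classes, capsule ring vs embryo, rather than background vs signal),
fills holes, opens, and fits the moment ellipse (centroid plus
2-sigma principal axes) of the largest component. A scene whose
brightest value is within 8 MADs of the background median is declared
egg-free and raises an error directing the user to the ROI-override
CSV. Overrides (`apply_roi_overrides()`) are validated against the
frame bounds and recorded with `source = "override"`.

Per-frame segmentation inside the ROI: 3x3 median filter, Otsu
threshold computed over ROI pixels only (here the two classes really
are background vs embryo), radius-1 binary opening, largest connected
component subject to a minimum-size floor of 0.1% of the ROI area
(floor at 5 px); exact size ties are broken by distance to the ROI
centre. Area is the pixel count of the component — equivalently the
polygon area of its traced pixel-edge boundary, matching the
contour-area convention of manual outline validation. Frames where no
component reaches the floor soft-fail (`valid = FALSE`, all measures
NaN) rather than erroring; frames where the embryo touches the ROI
boundary are kept but flagged (`boundary_touch`) for downstream
filtering. Because the threshold is data-driven, segmentation is
invariant to order-preserving affine intensity rescaling.

# Blockwise signals and Welch spectra

Grids of L x L blocks (L in {1, 2, 4, 8, 16}) are anchored to the
bounding box of the egg ROI, not to the moving embryo: frequency
analysis needs a fixed spatial reference so that a block's signal
means the same thing in every frame. Grid edges at level L are
`round(i * side / L)`, which makes the level-L edge set a subset of
the level-2L edge set; consequently the pixel-count-weighted mean of a
block's four children reproduces the parent exactly (the hierarchy
identity tested on every synthetic frame). Block means are taken over
pixels inside both the block and the ROI ellipse; blocks with no ROI
pixels are NaN.

Welch PSD conventions (fixed across the package): Hann window
(periodic), 50% overlap, per-segment constant detrend, one-sided
density normalization (`sum(PSD) * df` approximates the signal
variance, verified against a frozen independent reference
implementation and a variance oracle in the tests). The segment
length is `min(256, 2^floor(log2(2N/3)))` rather than the more common
`min(256, N)`: the latter degenerates to a single segment (no
averaging) whenever `N < 384`, while the chosen rule always yields at
least two overlapping segments and is identical (256) for all
full-length schedules considered here (N = 600 at 20 fps gives
df = 0.078 Hz; N = 2100 at 38 fps gives df = 0.148 Hz — both resolve
the physiological band). NaN gaps of up to 5 frames (failed
segmentation) are linearly interpolated before the transform; longer
gaps mark the whole recording's spectrum unavailable, which
propagates as NaN traits rather than an exception — Welch averaging
cannot honestly bridge long gaps.

Band energies integrate the PSD over contiguous bands (trapezoid rule
with interpolated band-edge ordinates, so refining a partition
preserves the total exactly). Default bands are contiguous 0.5 Hz bins
from 0 to Nyquist — wide enough for stable energies at both sampling
rates, narrow enough to separate the two species' cardiac bands (1.5
vs 3.5 Hz). Total Energy is the sum over all bands; relative energies
divide by it (NaN when the total is zero).

# Cardiac-rate identification

The heart occupies a small, moving part of the embryo and is not
visible in every recording, so the rate is sought across all blocks of
the spectrum set. Each available block contributes its in-band PSD
peak and its *prominence* — peak over in-band median PSD. A block
qualifies if:

* prominence >= 3 (the absolute quality floor; a flat spectrum's
  max/median for ~50 in-band bins rarely reaches 3),
* prominence >= 25% of the best block's prominence, and
* the peak rises above the spectral continuum in the 4 frequency bins
  just below the band.

The last two rules exist because gross embryo movement is the dominant
confounder: a random-walking bright embryo dumps broadband ~1/f²
power into every block it crosses, whose in-band maximum sits at the
band edge and keeps rising below it, whereas a beating heart is a
narrow line standing clear of the continuum. Raw peak *power* is
deliberately not the weight — movement power at a block edge can
exceed cardiac line power by orders of magnitude; normalized line
height (prominence) is what separates them. The reported frequency is
the prominence²-weighted median of qualifying blocks' peak
frequencies; the estimate is therefore always a Welch grid frequency.
When no block qualifies the estimate is NaN (heart obscured), never a
value clipped to the band edge. The default band 0.5–5 Hz excludes DC
and rotation drift below and Nyquist-adjacent noise above while
covering both species' typical rates; it is configurable per species.

Ontogeny models per embryo: ordinary linear regression (needs >= 5
finite estimates) or a continuous single-breakpoint piecewise-linear
model (>= 7), with the breakpoint chosen by exhaustive search over
interior observed timepoints minimizing residual SS. The exhaustive
grid is deterministic, trivially reproducible, and is its own
brute-force oracle; since the breakpoint model nests the line, its
RSS never exceeds the linear fit's. Recordings containing diapause
pauses are analysed as-is in the frequency domain (no pause excision):
a paused heart simply contributes less line power, and beat-to-beat
timing is outside this package's scope.

# Lethal end points and survival

Two death signatures, used stage-specifically:

* **Osmotic failure** (early, E3): apparent area rises rapidly (the
  embryo swells), then declines. The detector smooths the mean-area
  series with a rolling median (window 3) and calls the first interior
  local maximum that is >= 1.3x the pre-peak baseline median
  (delta = 0.3) and is followed by a sustained decline: no later
  smoothed value exceeds the peak (the smoothed peak may plateau for
  one step) and the post-peak minimum returns to near baseline.
* **Energy collapse** (later stages, and the E3 fallback): summed
  band energy stays below theta = 0.25x the baseline (median of the
  first k = 6 timepoints) for m = 3 consecutive timepoints; death time
  is the first timepoint of the run. The persistence requirement
  rejects diapause-like transients; a run still in progress at the end
  of observation is, by the same rule, not yet persistent — censored.
  An all-NaN baseline returns "undetermined" with a reason rather
  than a call.

Raising theta can only move calls earlier or leave them unchanged
(monotonicity, property-tested). Death time is the event onset, with
the recording interval as its resolution. Stage routing: E3 uses the
area peak with the energy drop as fallback ("combined" when the
fallback fires); E7/E9/E11 use the energy drop. Both E9 and E11 are
accepted as labels for the late stage set, since both namings occur in
practice for the same death signature.

Survival curves are simple empirical proportions (all embryos share
the observation window, so Kaplan–Meier weighting reduces to this);
censored embryos stay in the risk set to their last observation. LTp
is read under the step convention: the first grid time at which
survival has reached 1 − p/100 or below. The empirical curve jumps
exactly at death times, so with the default grid (the death times
themselves) the call is exact — a cohort all dying at 10 h has
LT50 = 10 h, and deaths at 2/6/10/14 h give LT50 = 6 h. Interpolating
linearly across a jump would instead smear a point mass (giving 5 h in
the first case), which is why it is not done.

# The synthetic generator

`synthetic_spec()` renders what the measurement chain needs to see,
not photorealism: dark background (mean 200), bright capsule ring
(1500), filled embryo ellipse (3000) growing linearly in area,
random-walk centroid motion clamped inside the capsule, and a heart
disc whose *intensity* oscillates as `I0 + a sin(2 pi f t)`. An
additive sinusoid suffices because the blockwise-spectral method reads
intensity, not geometry; it does not exercise shape-based beat
detection, which the package does not do. 16-bit output with a 200 vs
3000 contrast exercises the >8-bit dynamic range. Defaults: 128 px
frames (a desk-scale stand-in for 750 px acquisition ROIs), embryo
initial area 8% of the frame (embryos fill a substantial fraction of
the egg; small blobs would also inflate contour-discretization error
beyond what is representative), per-frame movement step SD 0.6 px,
Gaussian noise SD 30. Two death modes: osmotic (area x1.6 for two
recordings, then 40% shrink, all periodic signals silenced) and
cardiac cessation (area stable, heart and movement stop). Presets
carry the two study designs: `radix` (600 frames at 20 fps, hourly,
1.5 Hz heart) and `orchestia` (2100 frames at 38 fps, hourly, 3.5 Hz
with slow linear drift).

Every stochastic element is seeded and reported as ground truth
(per-frame centroid and heart-centre paths, analytic areas,
instantaneous rates, alive flags, death times in the experiment
manifest); identical spec + seed gives bit-identical frames.

`generate_trait_cohort()` emulates the *output* of the image pipeline
(per-timepoint area and energy series) for cohort-scale end point and
survival validation without rendering frames. Its death-time model is
a 4 h latency plus an exponential (rate 0.08/h): lethal stress takes
hours to kill, and a cohort alive at exposure start is exactly the
situation in which baseline-referenced detectors are meaningful — a
death in the first baseline window is undetectable by *any*
baseline-referenced rule.

What passing tests show, and what they do not: the generator covers
bimodal dark-field contrast, gross movement, narrow cardiac lines,
growth trends and the two death signatures. It does not model optical
PSF, focus drift, illumination flicker, overlapping embryos,
developmental shape change, or behavioural structure (spinning vs
crawling); recovery results here bound performance on clean data and
say nothing about such confounds.

# Problem sizes and runtime choices

The test suite renders 96–128 px frames and recordings of 12–600
frames; the cardiac-recovery battery uses 384-frame recordings (the
shortest length at which the 256-sample Welch segment is still used
with two overlapping segments) over {0.8, 1.5, 2.5, 3.5} Hz x
{20, 38} fps x 20 seeded replicates; end point and survival
properties use 60-embryo trait-level cohorts. The acceptance script
renders the two full-length schedules (600 frames at 20 fps, 2100 at
38 fps) end to end. These sizes are the package's validation design:
large enough that every estimator runs in its intended regime, small
enough to re-run routinely.

# Known limitations

* Movement is gross path length of the segmented centroid; net
  displacement is not reported (the centroid is the only tracked
  position, and within-recording path length is the measure matching
  per-recording "distance moved" summaries).
* Cardiac identification reports one frequency per recording; it does
  not separate two simultaneously visible rhythms, nor detect
  arrhythmia or individual beats.
* The energy-drop detector needs a live baseline window; deaths
  within the first `k` recordings are systematically missed.
* Block grids follow the egg ROI, so a heart that stays near a block
  boundary spreads its line across blocks; the level-1 (whole-ROI)
  block usually still carries the line because whole-ROI mean
  intensity is nearly invariant to embryo translation.
* Throughput is logged but never asserted; it is hardware-dependent.
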
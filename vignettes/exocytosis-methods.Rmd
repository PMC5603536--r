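---
title: "Methods: fusion-event detection, adhesion distances and the CSR null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fusion-event detection, adhesion distances and the CSR null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the models and procedures
it implements, the parameters that matter, and the design choices made
where the design was genuinely open. It states no empirical result that
the test suite and `scripts/acceptance.R` do not themselves compute.

## The optical model of a fusion event

An ecto-facing pHluorin reporter is quenched at acidic vesicular pH and
becomes fluorescent when the fusion pore opens. We model an event as
contributing nothing before its fusion frame `t0`; at `t0` an isotropic
2D Gaussian of integrated intensity `A` (counts) appears at a fixed
subpixel position, and for `t > t0` its width grows as

    sigma^2(t) = sigma0^2 + 2 D (t - t0),

free lateral diffusion of membrane-inserted cargo with coefficient `D`
(um^2/s), with integrated intensity conserved except for photobleaching,
applied per frame from the event's own appearance as
`(1 - bleach_rate)^(t - t0)`. This is the simplest model that reproduces
the two-part signature used downstream: a rapid rise and a growing FWHM
(`2 sqrt(2 ln 2) sigma`). Docked vesicles are the same model with
`D = 0`; moving endosomes additionally translate at a constant velocity.

Synthetic event defaults — `sigma0` 0.15 um, integrated amplitude 800
counts over a background of 100 counts (peak SNR roughly 15 at the
fusion frame), `D` 0.05 um^2/s — are chosen for testability: no public
dataset constrains the amplitude or width statistics of real events, so
the generator's role is to make every algorithmic contract measurable,
not to imitate a specific instrument.

## What the generator emulates, and what it does not

Emulated: the acquisition constants of a typical EMCCD TIRF setup
(pixel size 0.189 um, 6 frames/s, a 100-frame pre-bleach reference
period followed by photobleaching of the surface pool); an elliptical
cell footprint with smooth boundary modulation, brighter than the
off-cell glass (20% of the in-cell background outside the cell);
elongated elliptical adhesions at `fa_intensity` (default 5x) times
background, attenuated to a residual 10% after the bleach; Poisson shot
noise, Gaussian read noise (SD 2 counts), exponential photobleaching;
adhesion-proximal event placement with an exponential nearest-adhesion
distance law; and, for the endocytosis module, quench traces and
dual-label ramps with exact ground truth.

Not emulated: the evanescent-field depth decay of TIRF (membrane
topography near adhesions changes apparent brightness in real data — a
control the original experimental design addresses with a non-targeted
cargo, not computationally), camera gain calibration, docked-vesicle
trafficking kinetics, rolling-shutter effects, and drift of the stage
or cell. Passing tests therefore demonstrate correctness of the
computations under the stated model, not robustness to every real-world
artifact.

The `fa_proximal` sampler draws cell pixels weighted by the exponential
probability mass of a moving window (half-width 0.125 px) on the
distance transform, divided by the window's pixel occupancy, then
jitters uniformly within the pixel; its distance law is validated
against an independent per-draw rejection sampler by a two-sample KS
test. With `decay_um = 0` every event lands on the adhesion mask.

## Segmentation

Adhesions are segmented from the pre-bleach reference frame by
thresholding (`frame > threshold`), hole filling, and an area filter
(`min_area_px` 8, about 0.29 um^2 at 0.189 um/px). The default
automatic threshold is Otsu's method computed over the cell-footprint
pixels; the histogram routine is in-package because the restriction to
an arbitrary pixel subset is needed, and it is cross-checked against
EBImage's implementation in the tests. When Otsu's maximizer is a
plateau (an empty histogram valley), the plateau midpoint is used. For
the automatic cell footprint the reference histogram has three levels
(glass, membrane, adhesions) and plain Otsu can split off the bright
adhesion minority; when the above-threshold fraction is below 25% the
threshold is recomputed on the sub-threshold values — a two-stage Otsu
— then holes are filled and the largest connected component kept.

Polygon input is the primary path for the cell footprint in real data.
Vertices are in pixel-index space and a pixel belongs to the footprint
when its index point is inside or on the polygon boundary (so the
rectangle (10,10)-(50,50) rasterizes to 41 x 41 px). Everywhere else —
event coordinates, Gaussian fits, distances — coordinates are 0-based
continuous with pixel `(r, c)` spanning `[r, r+1)` and its center at
`(r + 0.5, c + 0.5)`. Self-intersecting polygons are rejected.

## Detection and classification

Candidates are local maxima of the forward frame difference after the
photobleach frame. The threshold is `rise_sigma_factor` (default 5)
times a robust per-pixel noise SD: the temporal MAD of each pixel's
frame differences, averaged over a 5x5 neighborhood. A per-pixel rather
than global scale matters because shot noise is larger on bright
adhesion pixels; the spatial average controls the MAD's own sampling
error. Two artifact guards follow, both scale-invariant: a candidate
whose neighborhood holds a negative difference stronger than the
candidate itself is vetoed (that is the positive ring of an already
spreading or moving source, not a new appearance), and a candidate must
remain above its pre-appearance baseline in the following frame (shot
noise spikes revert; fused vesicles persist). Candidates within
`min_separation_px` (5 px) and a 20-frame refractory window of an
existing candidate are merged. Fusion time is the first frame whose
difference exceeds threshold; sub-frame timing is not estimated (at 6
frames/s the timing error is bounded by ~0.17 s).

Classification fits an isotropic 2D Gaussian plus constant offset
(Levenberg–Marquardt, window 11 px, initialized at the candidate pixel
with `sigma` 1.5 px; integrated intensity `2 pi A sigma^2`) on each of
`spread_window_frames` (8) frames from `t0`, with the window tracking
the previously fitted center. A fit is rejected when the solver fails,
`sigma` exceeds half the window, the amplitude is non-positive, or the
window was clipped at a frame border. An event is accepted iff

* **rise** — the candidate pixel within 2 frames of `t0` exceeds the
  pre-fusion local level (median of the 10 preceding frames) by at
  least 5 robust noise SDs;
* **spread** — the FWHM trace over the spread window has positive slope
  with one-sided p < 0.05 by its t-statistic, with successful fits on
  at least 2/3 of the frames; and
* **stationarity** — the net drift, estimated as the fitted-center
  velocity times the window length, is at most 2 px. The velocity
  regression is weighted by localization precision `(peak/sigma)^2`: a
  spreading spot dims as it grows and its late centers wander, whereas
  a moving endosome keeps its brightness and shows a systematic
  velocity.

Rejections are labeled `no_rise`, `fit_failure`, `moving`, `no_spread`,
checked in that order. Aligned profiles average the fitted amplitude
and FWHM traces at each offset from `t0` over accepted events (SEM =
sample SD / sqrt(n)); traces start at `t0` because the pre-fusion
reporter is quenched and not fittable.

Detection performance is scored against the generator's ground truth by
greedy gated matching (3 px, +/-2 frames, best distance first); at
these gates and event densities a globally optimal assignment gives the
same pairs. The benchmark places events by CSR rather than
adhesion-proximally: with a 0.2 um decay the latter stacks events so
tightly on the same adhesions that a noticeable fraction of bursts are
true collisions (two fusions within ~3 px and a few frames), which
measures event overlap, not the detector.

## Distances and the CSR null

The distance from an event to the nearest adhesion is computed from the
Euclidean distance transform of the mask complement (pixel-center
metric: an event in an adhesion pixel scores 0). Bilinear interpolation
of the transform alone can err by up to ~0.7 px at medial-axis kinks,
so the interpolated value — an upper bound plus a known error margin —
bounds an exact local minimization over mask pixels; the result matches
exhaustive minimization to machine precision at every query point, at
distance-transform cost. Distances scale exactly with `pixel_size_um`.

The CSR null draws the observed number of events uniformly over the
cell-footprint pixels with subpixel jitter, 100 repetitions per cell by
default, reusing one distance transform. Per cell, the observed median
distance is compared against the mean of the per-repetition medians
(one simulated value per cell); groups of cells are compared by a
classic equal-variance two-sample Student's t-test (Welch's available
behind a flag). Whether to pool simulated distances or use per-rep
medians was an open choice; the per-rep-median convention keeps one
value per cell and repetition and is exposed in the result object.
With both groups constant and unequal, p is reported as the machine
epsilon sentinel rather than failing.

## Pool quantifications

`quench_fraction` takes the post-quench plateau (median from 3 frames
after the quench to the end — antibody binding is not instantaneous)
over the pre-quench level (median of the 5 preceding frames), with an
optional bleach correction that divides out an exponential fitted to
the log of the pre-quench segment; the result is clipped to [0, 1] and
is invariant to intensity scaling. Whole-cell sums include adhesion
pixels. `fa_ratio_timecourse` subtracts, per adhesion and frame, the
median of a 3-px annulus 2 px outside the label, making the ratio
invariant to flat additive background; ratios are undefined (NA) where
the denominator channel is at or below its noise floor. The activation
index is plain arithmetic, `(F - F0)/F_integrin`, homogeneous of degree
0; negative values are reported.

## Reproducibility and problem sizes

Every generator and the pipeline are pure functions of configuration
and seed: one root seed is expanded into independent per-purpose
streams (placement, fusion times, noise, CSR) so that changing the
number of events does not perturb the noise stream, and RNG state is
restored after each call. Two runs with the same configuration write
byte-identical `summary.json`.

The study-scale benchmark movie is 256 x 256 px, 300 frames with a
100-frame pre-bleach period, 30 events; the bundled five-cell spatial
experiment uses 192 x 192 px, 160 frames, 25 adhesion-proximal events
per cell with 100 CSR repetitions each. These sizes give stable
recall/precision and Monte Carlo estimates while keeping a full run in
the minutes range on one core.

## Known limitations

Sub-frame fusion timing and kiss-and-run discrimination are out of
scope; the drift veto is not a tracker. Overlapping events (two fusions
within a few pixels and frames) merge into one candidate — visible in
clustered placements — and events fusing within the spread window of
the movie end are excluded from alignment. TIFF I/O normalizes
intensities to [0, 1] with the scale recorded in a plain-text sidecar,
so absolute counts survive a round trip only through the package's own
readers. The quench bleach correction assumes mono-exponential
pre-quench bleaching of a stationary pool.
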
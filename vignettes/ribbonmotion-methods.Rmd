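---
title: "Methods: quantifying ribbon-precursor transport from 4D microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying ribbon-precursor transport from 4D microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribbonmotion)
```

## The analysis problem

Developing sensory hair cells assemble their presynaptic ribbons from small
mobile precursors. Live imaging of these puncta (and of EB3-labelled
microtubule plus ends) produces 4D stacks from which several quantities are
extracted: how each punctum moves (confined, Brownian, or directed), how far
it travels, in which direction relative to the cell's apical-basal axis,
whether two puncta fuse, and how many puncta occupy the apical versus basal
compartment. `ribbonmotion` implements that entire chain - simulation,
rendering, drift correction, detection, linking, MSD analysis, polarity,
fusion scoring, 3D counting, 2D areas and staging - with every stage
testable against synthetic ground truth.

## Motion model and the exponent alpha

For a track $r(t)$ sampled every $\Delta t$ seconds, the time-averaged mean
squared displacement at lag $\tau = k\Delta t$ is

$$\mathrm{MSD}(\tau) = \langle |r(t+\tau) - r(t)|^2 \rangle_t .$$

Fitting $\mathrm{MSD} = C\,\tau^{\alpha}$ by ordinary least squares in
log-log space over the first 25% of lags gives the anomalous-diffusion
exponent $\alpha$: $\alpha > 1$ indicates directed motion with velocity,
$\alpha = 1$ free (Brownian) diffusion, and $\alpha < 1$ confined or
subdiffusive motion. Only the first quarter of the curve is fitted because
the time-averaged estimator loses pairs (and hence reliability) at long
lags. Closed forms anchor the implementation: a noiseless ballistic track
has $\mathrm{MSD} = v^2\tau^2$ exactly (so $\hat\alpha = 2$ to floating
point), free diffusion has $\mathrm{MSD} = 6D\tau$ in 3D, and reflected
Brownian motion in a sphere of radius $R$ plateaus at $6R^2/5$ - the mean
squared distance of two independent uniform points in the ball. The test
suite verifies all three, the last against an independent Monte-Carlo
oracle.

Classification is binary - `directional` ($\alpha > 1$) versus `confined`
($\alpha \le 1$) - because the two reported classes must partition all
tracks; the boundary $\alpha = 1$ is assigned to `confined` (a measured
exponent of exactly 1 carries no evidence of transport). Tracks whose MSD
is zero at every fitted lag (stationary tracks) raise an explicit
degenerate-fit error and are excluded from classification with a reason,
rather than being given an arbitrary exponent.

A second, independent classification uses the track displacement - the
Euclidean distance between the first and last point. Displacements strictly
greater than 1 um flag a "long" track, the operational criterion for
directed transport; long tracks are further assigned a direction (base,
apex, or undetermined) and an axial position (above or below the nucleus).

## Synthetic trajectories: what the generator emulates

`simulate_track()` draws from the three motion classes the analysis is
meant to distinguish:

* **Brownian**: independent per-axis Gaussian increments of variance
  $2D\Delta t$.
* **Directed**: the same plus a deterministic drift $v\Delta t$ along a
  unit direction ("weak residual diffusion" around constant-velocity
  transport).
* **Confined**: Brownian proposals mirror-reflected at a sphere of radius
  $R_{conf}$ around the start point. The corral is a modelling choice (no
  confinement mechanism is specified by the assay); a reflected sphere was
  chosen because it has the closed-form plateau above, which makes the
  simulator itself testable. Steps are sub-divided whenever
  $2D\Delta t > (R/4)^2$ so a single sub-step cannot tunnel through the
  boundary, and a residual overshoot after one reflection is clipped to
  the boundary.

Localization noise is i.i.d. Gaussian per axis per frame with
$\sigma_{loc} = 0.02$ um by default - half the 0.04 um xy pixel of the
imaging convention. Comet fields place short directed tracks along the
cell axis with a wrapped-Gaussian angular jitter (s.d. 15 degrees by
default) and a configurable base-directed fraction `p_base`; fusion
scenarios build two tracks that converge at constant speed, become
coincident at a chosen frame, and then diffuse together.

What the generator does **not** emulate: photophysics (bleaching,
blinking), motion switching within a track, filament networks, deformable
geometry, or non-constant drift. Passing tests therefore demonstrate
correctness of the estimators under the stated motion models and imaging
noise, not robustness to every artefact of real recordings.

## Rendering and the image pipeline

`render_stack()` draws each emitter as an anisotropic Gaussian
($\sigma_{xy}, \sigma_z$) of fixed amplitude over a constant background,
with Poisson noise on signal plus background by default, at the
acquisition voxel size (0.04, 0.04, 0.17) um. The image pipeline then
mirrors the original macros:

* **Drift correction** is rigid translational registration of every frame
  to the first by FFT cross-correlation, with parabolic subvoxel
  refinement; frames are shifted back by the rounded offset.
* **Spot detection** is a Laplacian-of-Gaussian band-pass at the scale of
  the expected diameter (0.427 um for ribbons, 0.534 um for comets),
  local maxima with one-diameter minimum separation, and
  intensity-weighted subvoxel centroids. The reported quality is the LoG
  response normalized by the robust noise level (MAD) of the filtered
  volume; it is *not* numerically comparable to the proprietary quality
  statistic of commercial trackers, so quality thresholds do not transfer.
  Maxima within a (sigma + 1)-voxel border margin are discarded because
  the Laplacian is unreliable on replicated edges.
* **3D segmentation** thresholds the volume, optionally splits touching
  objects by a marker-based watershed on the exact (anisotropic) Euclidean
  distance transform, labels 26-connected components, and applies the
  object-counter size window (defaults min 0, max 183,500 voxels).
  Watershed seeds are EDT maxima, deduplicated per connected plateau
  (discretization makes EDT maxima flat) and then merged to a minimum
  seed separation (default 0.4 um, about one spot diameter). A
  shape-based watershed can only split a touching pair whose binary mask
  has a waist; overlapping blobs with a convex union remain one object.
* **2D areas** max-project along z, subtract background with a grayscale
  opening (separable running min/max, square window of radius
  `rolling_ball_radius_px`, default 50 px, replicate edges) - the
  rolling-ball idea implemented morphologically; it removes features
  narrower than the window and is exactly invariant to adding a constant.
  After thresholding and a 2D watershed split, object areas in um^2 are
  reported with the 0.002 um^2 minimum size filter.
* **Staging** converts a kinocilium z-slice count to height (0.425 um per
  slice) and bins it: early [0, 1.5), intermediate [1.5, 10),
  late [10, 18], mature (18, Inf) um. Within the bins the published
  thresholds are end-point inclusive as printed ("10-18" belongs to late;
  heights strictly above 18 are mature).

The intensity thresholds used in the counting assays (97 for the live
ribbon counter, 28 for the treatment series) are instrument-specific
arbitrary units; they are configuration defaults per modality profile,
not constants of the method.

## Track linking

Detections are linked frame by frame. Every active track predicts its next
position by constant-velocity extrapolation
$p = r_t + w\,(r_t - r_{t-1})$ with weight $w = 1$ by default (the
"autoregressive motion" idea), coasting through gaps at the last velocity.
Predictions and detections are matched by a globally optimal one-to-one
assignment (Hungarian algorithm on squared distances); links farther than
the gate are forbidden outright - there is no soft birth/death cost. The
gate and gap defaults follow the two assays: 1.13 um and 1 frame for
ribbons, 1.0 um and 3 frames for comets. Unmatched detections start new
tracks; tracks unmatched longer than the gap limit close; single-point
tracks are not reported. On small scenes the assignment is verified
against exhaustive enumeration of all possible matchings.

Track filters preserve the printed inequalities exactly: ribbons keep
tracks with at least 5 spots ("fewer than 5 excluded"), comets require
more than 5 (at least 6), and the MSD analysis requires at least 10.
The comet assay's automatic displacement threshold is reproduced as the
Otsu split of the track-displacement distribution - a declared
approximation of an undocumented proprietary threshold, not a claim of
equivalence.

## Polarity

Track angles are computed in the xy plane from the net displacement (end
minus start), as the absolute difference to the cell-axis angle folded
into [0, 180]: 0 degrees is straight toward the base, 180 toward the
apex. A track is base-directed iff its angle is strictly below 90 degrees
(the published count is printed as "tracks < 90 degrees"). Tracks with
zero net xy displacement are excluded with a logged reason rather than
assigned 90 degrees. The cell axis and nucleus plane are explicit inputs
(`cell_geometry()`): the original analysis measured them interactively per
cell, so no automatic estimate is attempted.

## Fusion scoring

An event requires that two objects can no longer be resolved separately -
operationalized as inter-centroid distance below `d_res_um` (default
0.3 um, just under the ribbon detection diameter) - and stay together for
at least `t_min_s` (default 300 s) or for the length of the remaining
timelapse. The detector looks for a *terminal* coincident run: a first
frame from which the pair stays within `d_res_um` at every later
co-existing frame. The merged object is carried by whichever track
survives longer, so both topologies are found: two tracks continuing
coincident, and one track terminating at the meeting while the survivor
continues. A pair that is close at every co-existing frame is treated as
a duplicate detection, not a fusion. The 5-minute criterion is converted
to frames as needed; at the slowest frame intervals used (100 s) it
corresponds to 3 frames. A known edge case: two tracks crossing exactly
at the final frame of the recording would satisfy the
remaining-timelapse rule; planted-scene tests avoid this geometry and
real analyses should treat single-frame terminal coincidences with
caution. Divisions (fissions) are not subtracted; the detector only
reports merges.

## Configuration, pipeline and reporting

`read_config()` validates a YAML configuration whose defaults are the
published assay parameters, rejecting unknown keys; the `eb3` profile
switches the linker, detection and filter defaults to the comet assay.
`run_pipeline()` executes link, filter, per-track analysis, polarity and
fusion scoring in order with exact attrition accounting (input = kept +
removed at every stage), and is deterministic for a fixed configuration
and input. `compare_groups()` reports per-group means and standard errors
of the summary fractions descriptively; inferential statistics are out of
scope.

## Numerical choices and problem sizes

* MSD pairs whose frame interval contains a gap-closed (missing) frame
  are excluded rather than interpolated, so the estimator never uses
  fabricated positions.
* The alpha fit uses at least 2 lags (`max(2, ceil(0.25 K))`), so
  minimally eligible 10-point tracks still fit.
* The fit is unweighted log-log OLS; weighting schemes change nothing for
  the exact power laws used as anchors and were not adopted.
* Direction calls replace the original manual scoring with an angle band:
  below 60 degrees base, above 120 apex, otherwise undetermined;
  configurable, and deliberately not validated against the published
  manual direction splits.
* Simulation-based checks use 500 tracks of 100 frames for exponent
  recovery, 200-500 tracks for ensemble MSD checks, and rendered scenes
  of at most ~240 x 175 x 20 voxels over 30 frames for the end-to-end
  pipeline test - sizes chosen so the full suite runs in well under a
  minute while keeping Monte-Carlo error far below the tested tolerances.

## Worked example

```{r example, eval = FALSE}
g <- cell_geometry(apex_point = c(5, 1, 1), base_point = c(5, 9, 1),
                   nucleus_plane = 4)
mix <- list(
  list(params = motion_params("directed", v = 0.05, D = 0.002,
                              direction = "base", sigma_loc = 0,
                              dt = 5, n_frames = 100), count = 30),
  list(params = motion_params("confined", D = 0.01, R_conf = 0.25,
                              sigma_loc = 0, dt = 5, n_frames = 100),
       count = 70))
ts <- simulate_trackset(mix, geometry = g, seed = 17)
report <- run_pipeline(read_config(), tracks = ts$tracks, geometry = g)
report$summary$directional_fraction # recovers the planted 0.30
```

## Known limitations

* The exponent classifier sees localization noise as apparent
  subdiffusion at very short lags; with the default noise (0.02 um) and
  the assay frame intervals this bias is negligible relative to the
  tested tolerances, but very slow tracks at fast frame rates would be
  biased toward `confined`.
* The EDT watershed cannot split overlapping spots whose combined mask
  has no waist; intensity-based splitting is deliberately not mixed in,
  to stay faithful to the binary-watershed procedure being reproduced.
* The linker has no merge/split awareness; merging objects are handled
  downstream by the fusion detector.
* Angle analysis is strictly 2D (xy); cells must be oriented so their
  axis lies in the imaging plane, as in the original assay.
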
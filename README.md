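# ribbonmotion

Trajectory and image analysis of presynaptic ribbon transport in
developing sensory hair cells.

## What this package is for

Hair cells of the zebrafish lateral line assemble their synaptic ribbons
from small mobile precursors that are transported toward the cell base,
largely along microtubules, and that can fuse with each other on the way.
Quantifying that process from 4D fluorescence timelapses requires a chain
of analyses: detecting puncta, linking them into tracks, classifying each
track's motion, measuring transport polarity against the cell's
apical-basal axis, scoring fusion events, and counting puncta per
compartment in 3D. `ribbonmotion` packages that chain for researchers
doing live imaging of intracellular transport - together with a synthetic
data generator (trajectories, comet fields, fusion scenarios, rendered
image stacks) so every stage can be validated against known ground truth
without any external data.

## The statistic at the core

For a track sampled every Δt seconds, the time-averaged mean squared
displacement at lag τ = kΔt is

    MSD(τ) = ⟨ | r(t + τ) − r(t) |² ⟩ₜ

Fitting `MSD = C τ^α` (log–log least squares over the first 25% of lags)
yields the anomalous-diffusion exponent α, which classifies motion:

| α          | motion class                       |
|------------|------------------------------------|
| α > 1      | directed motion with velocity      |
| α = 1      | Brownian (free) diffusion          |
| α < 1      | confined motion / subdiffusion     |

Closed forms anchor the implementation: ballistic tracks give α = 2
exactly, free diffusion gives MSD = 6Dτ, and diffusion confined to a
sphere of radius R plateaus at 6R²/5. Complementary classifiers: track
displacement (start→end distance, > 1 µm = "long"/directed), track angle
to the apical-basal axis (0° = toward the base, < 90° = base-directed),
and an operational fusion rule (two objects unresolvable below 0.3 µm
that stay together ≥ 5 min or to the end of the recording).

## Worked example

Simulate a labeled mixture - 30 directed tracks (v = 0.05 µm/s, weak
residual diffusion) and 70 confined tracks (corral radius 0.25 µm) in a
cell whose axis runs apex→base - then run the full pipeline:

```r
library(ribbonmotion)

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
run_pipeline(read_config(), tracks = ts$tracks, geometry = g)
```

which prints:

```
run_report
  filtering: 100 -> 100 tracks (0 removed)
  directional fraction: 0.300, long-track fraction: 0.300
  base-directed: 69/100 (69.0%)
  fusion events: 2
```

The directional fraction (share of tracks with fitted α > 1) and the
long-track fraction (displacement > 1 µm) both recover the planted 30%
exactly. The base-directed percentage counts all tracks below 90°; the
confined tracks contribute at chance, the directed ones all point to the
base. The two fusion events are pairs of confined tracks that this seed
happened to place within the 0.3 µm resolution distance - exactly the
"cannot be resolved separately and stay together" situation the detector
scores.

The polarity arithmetic on the published comet counts:

```r
base_fraction(angles_with_2069_of_2598_below_90)
# $n_base 2069, $n_total 2598, $percent 79.6, $percent_int 80
```

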
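# fishchain

Planar multi-fish body tracking with a chained-rectangle model.

Quantitative studies of collective fish behavior need the motion state of
every individual in a group, from top-view video of shallow water. Point
trackers lose the body geometry that swimming mechanics depend on, and
occlusions break identities. fishchain implements a complete tracking
system for this setting, aimed at researchers who want per-frame body
pose *and* stable identities for groups of visually similar fish:

1. **Body model.** Each fish is a chain of `n_r = 8` oriented rectangles
   `rec_1 … rec_8` (a long rigid head rectangle, then tapering body
   segments) hinged at joints `J_i`; a pose is an anchor plus eight
   orientations `θ_i`, with `|J_i − J_{i−1}| = len_i` by construction.
2. **Detection.** Background subtraction and thresholding yield fish
   blobs; each blob boundary is resampled to unit arc length and the
   nose is found as a positive curvature maximum,
   `C(i) = (φ(B_i+l) − φ(B_i−l)) / 2l` with `φ` the discrete tangential
   angle and `l = 8` px. Head orientation is the perpendicular bisector
   of the chord between the two support points; the body chain is fitted
   by greedy random search over candidate segment angles, keeping poses
   whose rectangle union covers ≥ 80% of the blob.
3. **Tracking.** A constant-velocity Kalman filter on the head state
   `[x, y, θ, x′, y′, θ′]` predicts each fish; trackers and detections
   are matched one-to-one by the Kuhn–Munkres algorithm under the cost
   `exp(−(NCC + V))`, where NCC compares head-rectangle image patches and
   `V = exp(k·cos(y − μ)) / (2π I₀(k))` (k = 4) scores orientation
   agreement. The body refit doubles as a veto: a tracked head whose
   body cannot be fitted is terminated.
4. **Relinking.** Fragmented tracklets are reconnected by a gated
   min-cost max-flow problem over tracklet endpoints (gap < 6 frames,
   endpoint distance < 80 px, cost `exp(D)·exp(−V)`), restoring
   identities across brief occlusions.

A seeded synthetic generator renders articulated fish sequences with
exported ground truth (nose, joints, identity, occlusion log), so the
whole pipeline is testable without any footage, and the standard metrics
(miss/error ratio, correct tracking ratio CTR, interruption rate AIT,
post-occlusion identification ratio CIR) are built in.

## A worked example

Simulate a small school, track it, and score the result against the
generator's ground truth:

```r
library(fishchain)

cfg <- sim_config(n_fish = 3, arena = c(1400L, 1400L), n_frames = 60,
                  seed = 1)
sim <- simulate_fish(cfg)

out <- run_pipeline(sim_frames(sim), fishchain_config(),
                    background = sim_background(sim), seed = 1,
                    truth = sim$truth, events = sim$events)
out$metrics
#> <fish_metrics> 3 fish x 60 frames
#>   miss ratio : 0.0000
#>   error ratio: 0.0000
#>   CTR        : 1.0000
#>   AIT        : 0.0000 per fish per 100 frames
#>   CIR        : n/a (no occlusion events)
```

Every one of the 180 fish-frames was detected with its nose within 10 px
of ground truth and a valid body fit (CTR = 1), no trajectory was ever
interrupted (AIT = 0), and no occlusions occurred (CIR not applicable).
`out$trajectories` is a tibble with one row per fish per frame — nose,
head midpoints, all seven joints, segment orientations and cover ratio —
ready for `autoplot()` or downstream kinematic analysis:

```r
head(out$trajectories[, c("frame", "id", "N_x", "N_y", "theta_1",
                          "cover_ratio")], 3)
#> # A tibble: 3 × 6
#>   frame    id   N_x   N_y theta_1 cover_ratio
#>   <dbl> <dbl> <dbl> <dbl>   <dbl>       <dbl>
#> 1     1     1  430   484.    2.77       0.977
#> 2     2     1  426.  482.    2.76       0.976
#> 3     3     1  422.  481.    2.80       0.983
```

Two canned scenarios reproduce the package's study conditions:
`demo_schooling()` (five fish, no occlusions — identity maintenance) and
`demo_crossings()` (ten fish, six scripted pairwise crossings —
fragmentation and relinking). A minimal command-line front end lives at
`inst/cli/fishchain.R` (`simulate` and `run` subcommands).

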
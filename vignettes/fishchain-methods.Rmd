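---
title: "Tracking the waving bodies of multiple fish: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking the waving bodies of multiple fish: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

fishchain tracks groups of fish swimming in shallow water from top-view
grayscale video, recovering not just a point per fish but the full body
geometry — a chain of oriented rectangles — in every frame, while
maintaining individual identities through occlusions. This vignette
explains the models, the numerical choices, and what the synthetic-data
experiments do and do not demonstrate.

## The body model

A fish is modelled as a chain of `n_r = 8` oriented rectangles, the first
(50 x 35 px) covering the rigid head and seven more (30 px long, widths
tapering 35 to 8 px) covering the flexible body. Rectangle `i` hinges at
the back-edge midpoint `J_{i-1}` of its predecessor, so a pose is fully
described by one anchor point and eight orientations; chain-length
consistency (`|J_i - J_{i-1}| = len_i`) holds by construction. The sizes
are fixed per run: the fish in one tank are of similar size, and an
optional `scale_spec()` hook covers the rest. Rectangle widths are
centered on the segment axis; the coordinate convention is image pixels
(origin top-left, y down) with angles in the mathematical convention on
(x, -y), so a single sign rule covers curvature, orientation similarity
and rasterization.

A pixel belongs to a rendered rectangle when its center lies inside the
polygon, half-open on the far side of each axis: deterministic,
orientation-robust, and abutting rectangles never double-claim a pixel.
Poses partly outside the canvas are clipped silently.

## Detection

Each frame is background-subtracted (the background is the pixel-wise
mean of many frames, or a supplied plate image) and thresholded at 80
gray levels — half the plate/fish contrast of the synthetic imaging
conditions. Connected components above a quarter of the model's body
area are kept. Each component's closed boundary is traced and resampled
to unit arc spacing, wound counter-clockwise in (x, -y).

The nose is the boundary point of maximal positive curvature at the
front of the fish. Curvature at a boundary point is the wrapped
difference of the tangential angles eight arc units to either side,
divided by the sixteen-unit window. Two numerical details matter:

* the tangential angle is unwrapped cumulatively along the curve before
  differencing, which removes the +/- pi ambiguity a pairwise wrap
  suffers at sharp tail tips and makes the discrete total-turning
  identity (sum of C times arc = 2 pi) hold exactly for simple curves;
* each supra-threshold curvature maximum (threshold 0.08 rad/px,
  non-maximum suppression over a 40 px window) is refined to the
  centroid of its supra-threshold run — rasterization noise makes the raw
  argmax wander across a blunt maximum while the excess-curvature
  centroid stays on the anatomical tip — and candidates must pass a tip
  test (the boundary 20 px to either side must recede at least 10 px
  behind the point), which rejects the shallow convex corners a strongly
  bent body produces. Concave intersection corners between overlapping
  fish have negative curvature and are never candidates.

For an isolated fish the profile shows exactly two maxima; the lower one
is the nose (the snout is blunter than the needle-like tail tip), the
higher the tail. Blobs with any other number of maxima are treated as
potentially occluding fish and every candidate is passed downstream,
where implausible ones die by the cover-ratio filter or by failing to be
associated.

Head orientation is the perpendicular bisector of the segment joining
the boundary neighbors eight arc units either side of the nose, averaged
over a small family of support arcs (6-12 px) to damp a degree or two of
rasterization tilt; support points are smoothed over +/-3 boundary
points. The head rectangle is placed with its front edge 10 px beyond
the nose, which keeps the nose strictly interior.

Body fitting is a greedy random search: for each rectangle in turn, 128
candidate angles are drawn uniformly, and the candidate covering the
most foreground pixels not yet claimed by earlier rectangles wins;
near-ties (within 0.5% of the best count) resolve towards the smallest
angular change from the previous segment, since the body bends smoothly.
Counting only unclaimed pixels prevents the degenerate fold-back in
which a body rectangle doubles back over the head. A pose whose final
cover ratio — the fraction of its component's pixels inside the
rectangle union — falls below 0.8 is removed.

## Tracking

The head state is a six-vector: position of `J_1`, head orientation, and
their values one frame earlier. The transition matrix realizes the
constant-velocity recursion `x_t = 2 x_{t-1} - x_{t-2}` (the same
extrapolation used when coasting); the observation picks out the current
triple. Process and observation noise are unpublished; the defaults
(`Q = diag(1, 1, 0.01)` twice, `R = diag(2, 2, 0.02)`) reflect the
per-frame deviation from constant velocity at 100 fps-equivalent motion
(lateral acceleration of order turn-rate times speed, well under a
pixel per frame squared).
The initial covariance equals `Q`: keeping it tight means a grossly
wrong first association cannot jump a young tracker's state all the way
onto another fish — the update lands between the two and the body-fit
veto catches it. All angular arithmetic wraps differences into
(-pi, pi]; with exactly zero noise the update degenerates, and the
implementation adopts the measurement exactly in that limit, which makes
noise-free constant-velocity tracking reproduce ground truth to float
precision.

Data association minimizes the summed cost `exp(-(NCC + V))` over
one-to-one tracker/measurement pairs (Kuhn-Munkres with dummy padding;
the solver is validated against exhaustive permutation enumeration).
`NCC` is the energy-normalized cross-correlation between the tracker's
stored head patch and the measurement's patch, both sampled over the
head rectangle rotated to horizontal; `V` is the von Mises density (k =
4) of the predicted orientation around the measured one. Pairs below the
gates (NCC < 0.6, V < 0.05) are forbidden. Notably the cost contains no
positional term: on texture-poor backlit silhouettes the appearance term
is weakly discriminative (the bright plate dominates the patch energy in
any normalization we measured), so two distant fish whose headings
momentarily agree can swap. The system's defenses are downstream: a
swapped update lands off-body, the body-fit veto terminates both
trackers, the vetoed measurements immediately seed fresh trackers in the
same frame (they were valid detections that are now unassociated), and
relinking — which does use distance — reconnects the fragments correctly.
This veto-respawn-relink loop is what makes identities stable in the
occlusion-free experiments below.

Associated trackers get a standard Kalman update and a body refit in
which candidate angles are drawn from a von Mises (k = 4) centered on
the previous frame's segment orientations. Unassociated trackers coast
by linear extrapolation for at most 5 frames; an unassociated track
shorter than two frames is discarded as a detection error. A tracker
whose refit covers less than 80% of its component is terminated — the
veto that removes wrong head tracks.

## Relinking

Tracklet endpoints form a flow network: source to each tracklet, each
tracklet to sink, and a candidate link from tracklet i to j iff the gap
`st_j - ed_i` lies in (0, 6) frames and the endpoint head-joint distance
D is under 80 px. Link cost is `exp(D) * exp(-V)` with V comparing the
endpoint orientations (k = 4); body geometry is deliberately excluded,
as it changes too much across a gap. Because every tracklet must end up
in exactly one trajectory, a total flow of f is equivalent to choosing
`n - f` links forming vertex-disjoint chains; the minimum-cost choice is
found by successive shortest augmenting paths (Bellman-Ford on the
residual graph, ties towards the lowest edge id, validated against
brute-force enumeration on small graphs). When the fish count is
unknown, the largest feasible number of links is taken (every gated link
costs something, so without the coverage requirement a cheapest flow
would never link at all). Tracklet ends include coasted frames — a
tracker lost during an occlusion records its extrapolated endpoint, so
the gap measured by the gate is the unobserved span rather than the
(longer) span since the last detection; coasted frames carry no poses in
the output.

## The synthetic generator

The generator emulates backlit shallow-water imaging: plate gray 200,
fish gray 40, Gaussian sensor noise of sigma 4 (pre-generated as a noise
field applied at a frame-specific cyclic shift, which keeps frames
deterministic and mutually decorrelated without drawing millions of
variates per frame). Each fish's joints follow the recent path of its
head joint, with a sinusoidal undulation (amplitude 0.25 rad, period 20
frames, per-segment phase lag 0.8 rad) superimposed segment-wise — a
backward-travelling propulsive wave with exact chain lengths. Speeds are
2.5-5 px/frame; heading is a bounded random walk (sd 0.03, cap 0.06
rad/frame — larger turn rates at these speeds bend the path tighter than
the body can follow, producing self-intersecting silhouettes); fish
steer away from walls and from each other's bodies, with wall avoidance
taking precedence (being pushed into a wall must not happen) and a
position clamp as backstop.

The silhouette is a smoothly tapering ribbon around the joint chain:
mitered cross-sections at the joints using the following rectangle's
width (so the stepped rectangle model always covers the body laterally,
and the sides show no spurious convex corners), a conical snout of side
slope 0.5 ending in the ground-truth nose (in-window curvature about
0.138 rad/px) and a sharper tail taper (slope 0.18, about 0.174 rad/px):
an isolated fish therefore shows exactly the two curvature peaks the
detector expects, with the tail peak reliably higher. Each fish also
carries a smooth pigment banding (fish-specific wavelength 36-60 px and
phase, anchored to the rigid head) — without some individual appearance
the NCC term of the association cost carries no information at all on
identical silhouettes. These shape choices emulate what matters to the
method (two boundary tips, a rigid textured head, a flexible body);
fins, photorealistic texture and 3-D attitude changes are not modelled,
so success here does not establish performance on real video — it
establishes that the implementation is faithful and self-consistent.

Scripted crossings stage brief occlusions: one fish of a pair glides
straight through a crossing zone while the other, staged on a roughly
perpendicular course, arrives just before the first fish's tail clears.
Both glide (suspend undulation, burst-and-glide style) through the
crossing window so the contact duration (~8 frames) is not jittered by
the tail beat; the crossing fires at its earliest feasible time given
both route lengths, so neither fish loiters (loitering at the speed
floor produces path curls). The occlusion log records actual pairwise
silhouette intersections, not the script's intent. An 8-frame occlusion
is long enough to terminate both trackers (over 5 lost frames) and short
enough that the relinking gates can reconnect the fragments.

## Problem sizes and what the experiments show

The packaged experiments use: 50 single-fish frames (512 px arena) for
detection accuracy; five fish for 200 frames in a 1400 px arena for
identity maintenance (at this density the avoidance behavior keeps
silhouettes from ever intersecting — at roughly double that density,
close passes become frequent enough that the position-free association
cost produces occasional unrecoverable swaps); and ten fish for 370
frames in a 2000 px arena with six scripted crossings for relinking. On
the staged scenario the long parallel approach legs hold many fish at
nearly equal orientations, a degenerate regime for the orientation term;
the resulting association-tie churn is absorbed almost entirely by the
veto-respawn-relink loop (about 99% of excess fragments reconnect, with
no incorrect links), but when such a churn break happens to abut an
occlusion the combined gap can exceed the 6-frame relinking gate and one
crossing's identities are lost — the identification ratio over the
staged events falls short of 1. We report this as a genuine property of
the method's cost structure rather than tune the scenario around it.

## Parameters

Published model constants: the rectangle sizes; k = 4 for both von Mises
uses; cover threshold 0.8; coasting limit 5 frames; relinking gates 6
frames / 80 px; evaluation tolerance 10 px. Calibrated here (no
published value): binarization threshold 80; minimum blob area (25% of
model area); resampling spacing 1 px (making "eight unit arc lengths"
eight points); curvature threshold 0.08 rad/px; suppression window 40
px; nose margin 10 px; 128 candidate angles per rectangle; association
gates 0.6 / 0.05; the Kalman noise covariances and initial covariance.
Every configuration object carries a provenance tag per parameter so
emitted configs distinguish the two classes.
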
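---
title: "Multi-cue player and ball tracking: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-cue player and ball tracking: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(courtTrack)
```

courtTrack tracks the four players and the ball in fixed-camera recordings
of court sports such as beach volleyball. This vignette explains the models
the package implements, the parameters that matter, and the design choices
made where the method leaves room.

## Geometry

A fixed camera observes the planar court, so image pixels and court-plane
meters are related by a 3x3 projective homography. Four user-clicked court
corners paired with the court's metric corners ((0,0), (W,0), (W,L), (0,L)
for a W x L court; 8 x 16 m by default) determine the map exactly;
`estimateHomography()` solves the normalized direct linear transform. All
tracker state lives in world coordinates; image quantities are derived
per frame through the homography. `localScale()` gives the pixel length of
a one-meter segment at a court point — larger in the front of the court
than in the back — and sizes every player bounding box (a square of
`heightM` = 2 m, bottom-center anchored at the foot point, split into 4
stacked subwindows) and the expected ball area.

Pixel coordinates are 0-based with the origin at the top-left corner and y
pointing down; world coordinates are meters with y along the court length.
These conventions are asserted throughout the tests.

## Background model and cue images

A per-pixel Gaussian mixture with up to 16 modes learns the background.
Only every 10th frame feeds the model, so walking players average out
between inputs, and every 3rd model input is replaced by the current
background image, which keeps lingering players from being absorbed. The
learning rate doubles as a change detector: while the foreground fraction
exceeds `fgSpikeFraction` (0.3), the high rate (0.1) replaces the normal
rate (0.01) so global illumination steps are re-learned quickly; the
acceptance suite measures the speedup directly.

Two binary cue images are derived per frame. The *foreground mask* is the
thresholded (25/255), luminance-weighted absolute difference between the
frame and the background, cleaned by a 3 x 3 morphological opening
(EBImage); applied to the frame it zeroes all background pixels. The
*movement mask* applies the same binarization and opening to the difference
between consecutive frames, so only moving objects survive; a config switch
(`movementSource`) can instead difference the two frames' foreground masks,
since the source method can be read either way.

The pipeline driver seeds the mixture with the per-pixel temporal median of
strided frames before tracking starts: the model's first ingestion
dominates its memory, and the median of a dozen spread-out samples is free
of the moving players, whereas a raw first frame would imprint them.

## Appearance model

Player appearance is a one-dimensional HSV histogram: an N_H x N_S jointly
binned hue-saturation block with N_V value bins appended; the 10/10/10
default gives B = 110 bins. Every masked pixel contributes one chroma count
and one value count (`sum(bins) == 2 * nPixels`). Histograms over any
axis-aligned rectangle can be read from an integral histogram — a per-bin
cumulative count image — with four corner lookups, bit-identical to direct
computation; the rigid-grid tracker exploits this because its particle
boxes overlap heavily.

Reference histograms are extracted once, from the *masked* calibration
frame, per subwindow of each player's box. Masking matters: without it the
net and sand would enter the reference and be expected at a fixed body
height forever after. Subwindow histograms are compared with the
Bhattacharyya distance D = sqrt(1 - sum_b sqrt(p_b q_b)); the per-subwindow
score is s_k = c (1 - D_k) with c = 100 keeping products away from
underflow (an exponential form exp(-lambda D^2) is available behind
`weightForm`; per-frame max-normalization makes any monotone form
order-equivalent). The upper three subwindows are coupled tightly by
multiplying their scores — a mismatch in any one vetoes the product — while
the lowest subwindow (lower legs, often spread or off-box) is only added.

A subwindow whose *reference* histogram is empty (the top band above a
short player's head, or legs the foreground mask missed at calibration)
carries no color information, so it is skipped in the coupling rather than
treated as a permanent mismatch. The skip depends only on the reference, so
it is identical for every hypothesis of a set and cannot reorder them.

The two count cues are the number of nonzero foreground (respectively
movement) pixels in each subwindow, normalized to the subwindow width. The
total weight of a hypothesis is `alphaColor * color + alphaMask * mask +
alphaMov * mov` = (1.0, 0.4, 0.1) after each cue is normalized to the
set's per-frame maximum.

## The two player trackers

**Classical particle filter.** Each player has a set of 30 particles
(world positions). Per frame: weight every particle with the three cues,
estimate the state as the weighted mean, then resample roulette-wheel
style (multinomial, probability proportional to weight) with isotropic
Gaussian jitter — 0.2 m normally, 0.04 m for particles within the top 0.1%
of the set's maximum weight, which keeps a tight kernel on the current
best hypothesis while the rest of the cloud explores.

**Rigid grid.** The integral-histogram tracker keeps a fixed world-space
grid (6 rows x 7 columns over 2 x 2 m by default; the evaluation presets
put 15 or 33 particles in 3 rows of 5 or 11 columns) of offsets around the
anchor. The particle rows keep the grid's row pitch but are centered on
the anchor so the weighted-mean estimate is unbiased; the rows above them
contribute appearance context through each particle's subwindowed box.
Cell weights get an additional quadratic positional factor
1 - beta ((col - center)/maxOffset)^2 (beta = 0.5) favoring the center
columns. The anchor moves to each frame's weighted-mean estimate; offsets
never change.

**Confusion safeguard and recovery.** When two trackers' estimates stay
within `guardOverlapDistM` for more than 10 consecutive frames they are
deemed to track the same player, and the one with the smaller mean raw
color score is re-initialized uniformly. Two notes on the defaults:

* `guardOverlapDistM` is 1.0 m — half the 2 m bounding-box width. Two
  trackers sharing one blob settle at stable offsets of 0.6–0.9 m (each
  pulled to a different side of the blob by its own normalization), so a
  0.5 m radius never fires on exactly the failure it is meant to catch;
  1.0 m means "both estimates inside one player's box".
* Re-initialization searches the player's *team half* rather than the full
  court. The safeguard targets same-team identity mix-ups (teammates dress
  alike and share a half), and pre-structured clips tell us each player's
  side; searching the opponent half only invites cross-court captures.
* A searching (lost or re-initialized) set relocks on **color evidence
  alone**: the mask and movement counts do not discriminate players and
  would latch the cloud onto the nearest moving blob.
* The rigid grid is local — 2 m around its anchor — so it sweeps a coarse
  (0.75 m) lattice of its home region with the color score: every frame
  while searching (it cannot cover the court from one anchor), and every
  10th frame while tracking, yielding to a position outside its own reach
  that scores at least twice its *recent* color evidence (an exponential
  moving average — a briefly occluded target must not make the grid yield
  to a weaker distractor). The sweep is what the particle cloud gets for free
  from its spread: without it a grid captured by a similarly colored
  distractor — typically a teammate's upper body or legs, whose ground
  back-projection sits a meter or more from the teammate's feet and hence
  outside the guard radius — never notices that the true player matches
  far better a few meters away.

Each tracker owns a private RNG stream derived from the run seed and its
player id, so results are bit-reproducible and independent of the order in
which players are updated.

## Ball detection and trajectories

The ball is found in the movement mask only — its colors blur at 25 fps
and its roundness is lost, so color and shape cues are useless. Candidates
are 8-connected components whose area lies within [0.25, 4] times the
expected blob area, where the expected area is *two* ball cross-sections
(`diffFactor = 2`: the frame-difference image of a moving ball contains up
to two disks — the appearing and the vanishing position) at the 21 cm ball
diameter scaled by `localScale()` at the blob's back-projected ground
point. Each candidate must also be isolated: the inner 40 x 40 px square
centered on the centroid holds more than Q = 30 nonzero pixels while the
outer 60 x 60 px square holds at most R = 5 more. The literal reading
bounding the outer count by Q + R is available (`isolationMode`), but it
also rejects large isolated blobs, so the inner-count + R form is the
default.

**Trajectory growth.** Ballistic image motion is a line in x over frames
and a parabola (negative curvature) in height over frames. A trajectory
seeds when three candidates from nearby frames lie within 20 px of each
other — read as a chain over consecutive candidates, since a fast ball
legitimately moves ~15 px per frame — and are collinear in the x–t
scatter (2 px tolerance). Growth predicts the next position, absorbs the
nearest candidate within 10 px (ties toward lower x, then lower y), and
refreshes the least-squares fit, but only if the refreshed fit keeps the
RMS residual below 3 px: points beyond a ball contact bend the parabola
and are rejected, which makes trajectories end at contacts instead of
bleeding across them. More than three consecutive missing frames terminate
a trajectory. Among time-parallel trajectories the one with the most
members (then the lowest residual) is selected; neighboring arcs
legitimately share a frame or two around the contact (the contact-frame
candidate belongs to both), so only overlaps of more than two frames count
as parallel. Selected trajectories are finally extrapolated: neighbors
meet at the intersection frame of their x–t lines (or the gap midpoint),
and the first/last trajectories extend to the clip bounds.

**Hough-line alternative.** Candidate positions are plotted over time as
x–t and y–t scatter images. Near-horizontal point lines (|slope| below 5
degrees) are static flicker and are removed — with the caveat, preserved
faithfully, that this can also delete true arc candidates
(`skipHorizontalRemoval` exposes the switch). Non-horizontal lines with at
least 20 px length and at most 10 px point gaps (a 1 px / 1 degree Hough
accumulator) group the remaining candidates; each group gets its own
line + parabola fit, and neighboring groups are joined when their x–t
lines intersect inside the inter-group frame gap with height models
agreeing within 15 px there.

**Contacts.** A ball contact is the intersection of consecutive height
parabolas: solve the quadratic difference, keep the real root closest to
the gap midpoint, reject roots outside the gap extended by 15 frames. The
serve cannot be an intersection, so the first trajectory's initial frame
is the first contact. Events are reported with fractional and rounded
frames; evaluation uses the rounded value.

## Evaluation protocol

A player frame is correct when the estimate is within 0.5 m world distance
*or* 20 px (the pixel radius matters in the back of the court where a
meter is few pixels). Evaluation starts at the first frame where all four
players are correct for two consecutive frames and then samples every 3rd
frame. Same-team identity swaps can be allowed (`allowTeamSwaps`). Ball
frames are correct within 20 px, reported against both total and tracked
frames; contacts are correct within strictly less than 10 frames, matched
greedily one-to-one in time order.

## The synthetic scene generator

No recordings ship with the package, so `generateScene()` builds seeded
scenes with exact ground truth: a static sand-textured background under a
fixed perspective homography, four players rendered as four-band colored
rectangles sized by the homography walking waypoint paths (ping-pong, so
they keep moving), a white ball following exact line/parabola arcs between
scheduled contacts with the leading coefficient fixed by gravity scaled
into pixels and frames (a2 = -g/2 * pixels-per-meter / fps^2), plus
optional global illumination steps, static occluder rectangles and
spectator flicker. Ground-truth pixel positions are exactly
`worldToImage()` of the world truth; the final schedule row only ends the
rally and is not counted as a recoverable contact (there is no following
arc to intersect).

The generator emulates what the cues need — distinct band colors,
foreground/background contrast, ballistic ball motion, mutual-occlusion
path crossings — but not articulated limbs, motion blur, shadows, camera
shake or net occlusion of the ball. Passing tests therefore demonstrate
the machinery is correct and self-consistent, not that real-match accuracy
would reach the same levels; on real footage the published experience is
roughly 80% player accuracy and 50% ball accuracy, far below the
near-ceiling numbers on clean synthetic scenes.

Problem sizes used by the tests and the acceptance script: the four-player
benchmark runs 300 frames at 320 x 240 with two engineered path crossings
(speeds 0.8–1.0 m/s); ball scenes run 230 frames at the full 640 x 480
(the 40/60 px isolation windows and Q = 30 are calibrated for that video
geometry); unit tests use much smaller frames with directly constructed
cue bundles.

## Numerical choices and known limitations

* Homography estimation normalizes coordinates (centroid/scale) before the
  SVD solve; corners reproduce to 1e-9 m and round trips to 1e-6 px.
* Least-squares fits center the frame index before solving, so parabola
  recovery stays exact (1e-9 relative) at frame indices in the hundreds.
* Ties in candidate absorption and root selection are broken
  deterministically (lower x, then lower y; root nearest the gap
  midpoint).
* The movement mask carries a half-frame positional lag when the two
  motion disks merge (the centroid sits between the old and new
  positions); contact estimates absorb this below the one-frame level.
* A ball hanging near its apex with little horizontal motion can vanish
  from the movement mask for several frames; arcs with lateral travel
  keep it visible, but slow vertical serves can fragment.
* Players who stand still for long stretches are eventually absorbed into
  the background; the feedback path delays but does not prevent this.
* The evaluation's front/back split is derived from the reference mean
  court depth per player unless specified.
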
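---
title: "Space and control from tracking data: the models behind spacekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Space and control from tracking data: the models behind spacekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

spacekit quantifies *spatial control* in soccer: how much of the pitch a
player or team can influence at a moment in time, how valuable that ground
is, and how much space individual players create for their team around
passing moments. This vignette describes the models, the choices behind
them, and what the synthetic-data experiments do and do not establish.

## Coordinates, data model, alignment

All positions live on a 105 x 68 m pitch centered at the origin
(x in [-52.5, 52.5], y in [-34, 34]); the team under analysis attacks
toward +x, because the pitch-value surface needs a fixed goal. Tracking is
one row per agent per frame at 25 Hz (`read_tracking()`, `# fps:` header
overrides); events are passes and shots with initiation and reception
timestamps (`read_events()`). Frame gaps are hard errors, never
interpolated — interpolation silently corrupts the finite-difference
velocities every downstream model consumes. Events are aligned to the
nearest frame, with equidistant ties resolved to the *later* frame for
determinism, and a configurable 0.1 s rejection threshold.

Ball possessions (`group_possessions()`) close when the passing team
changes or a shot occurs, and are successful exactly when they end with a
shot by the possessing team. The segmentation rule itself is a documented
package choice: event feeds rarely state possession boundaries, and
different providers disagree; all downstream metrics only require that the
rule is deterministic and that success means "ended in a shot". Possessions
with fewer than three passes are flagged rather than deleted, since the
outcome analyses discard them but other uses may not.

## Player movement models

The central object is a per-player, data-driven movement model. From the
tracking we extract *triplets* (p\_{t-delta}, p\_t, p\_{t+Delta}): the first
leg (delta = 0.2 s) encodes the initial velocity, the endpoint is where the
player actually got to after Delta seconds. Each triplet is translated so
p\_t is the origin and rotated so the initial movement points along +x; the
endpoint becomes (d cos theta, d sin theta), where d is the length of the
second leg and theta the signed angle from the initial to the realized
movement direction (so a left turn lands at positive y). The transform is
invariant under rigid motions of the raw trajectory, which the tests check
explicitly.

Endpoints are grouped by initial-speed bin — standing [0,1), walking [1,7),
jogging [7,14), running [14,20), sprinting [20,Inf) km/h — and by horizon
Delta in T = {0.2, 0.4, ..., 5.0} s (passes complete within 5 s, so larger
horizons are never queried). Each populated (bin, Delta) cell is summarized
by a Gaussian-kernel density estimate:

* **Bandwidth.** Diagonal Scott rule by default, optionally rescaled by
  k-fold cross-validated held-out log-likelihood (`bandwidth = "cv"`). Both
  are deterministic; we deliberately avoid stochastic global optimizers for
  a two-parameter smoothing problem. Bandwidths are floored at 0.05 m so a
  degenerate endpoint cloud (a constant-velocity walk) still yields a
  proper density.
* **Cell occupancy.** Cells with fewer than `min_count = 50` endpoints are
  marked unavailable; a query falls back to the nearest available horizon in
  the same bin, with a message. Fifty endpoints is a pragmatic floor for a
  2-D KDE whose queries are density *ratios*.
* **Mode.** The main mode is found by Gaussian mean shift with bandwidth
  equal to the KDE bandwidth, initialized at the endpoint mean, tolerance
  1e-4 m, at most 500 iterations. Tests compare it against a brute-force
  density argmax on a centimeter grid.

Normalized *player influence* at a query point is the cell density at the
point (after translating and rotating the query into the player's local
frame) divided by the density at the mode — a number in [0, 1] that equals
1 exactly at the mode. A stationary player has no defined heading; we set
theta = 0 and rely on the standing bin, whose endpoint cloud is close to
isotropic, so the convention is immaterial.

## The Gaussian baseline

For comparisons the package ships the classical bivariate-normal influence
model: mean p\_t + 0.5 v, covariance R V V R^-1 with R the rotation to the
movement heading and V diagonal with entries (r + r s)/2 and (r - r s)/2,
s = (|v|/v\_max)^2. The radius r grows with distance to the ball; the
literature gives the map only graphically with range [4, 10] m, so the
default is a logistic in d (midpoint 15 m, scale 3 m) rescaled so r(0) = 4
exactly and r -> 10; the form is configurable. Two numerical choices:
the published velocity term is a bare displacement difference, which we read
as m/s (displacement over delta) with mu = p + 0.5 s * v for dimensional
consistency; and at |v| = v\_max the second scaling entry vanishes, so V
entries are floored at 1e-6 m, which keeps the closed forms of the
non-degenerate cases exact. Both influence models sit behind one backend
interface (`gaussian_backend()`, `datadriven_backend()`) and are drop-in
interchangeable everywhere.

## Pass time, pitch control

How long does a player have to reach a pass? We regress observed pass
duration (reception minus initiation) on the passer-receiver distance at
initiation, using completed passes only (reception time is undefined
otherwise) and dropping durations above 5 s. A Yeo-Johnson power transform
is applied to the *predictor* only — its usual role is a feature
transformation — with lambda chosen on a grid by validation
MSE on a held-out 20% split. Predictions are clipped to [0.2, 5] s and
snapped to the nearest horizon in T, ties upward.

*Pitch control* at a point is tanh of the difference of summed team
influences. Each player's horizon comes from the pass-time model applied to
her current distance to the ball; the ball carrier gets the smallest
horizon (the carrier needs no pass to be where she is — there is no agreed
convention, so this is a package choice, configurable via `carrier_id`). tanh keeps values in [-1, 1] and makes the team-swap
antisymmetry exact, which the tests assert identically, not approximately.

## Defensive influence, pitch value, space quality

Defenders reveal which ground matters: summed (capped at 1) influence of
the defending team's outfield players is the *observed defensive
influence*. A feed-forward network fn(ball, p) — two hidden layers of 64
ReLU units, dropout 0.1, Adam on mean squared error, features standardized,
outputs clipped to [0, 1] at inference — learns that surface as a function
of ball position from (frame, grid node) training rows on a coarse 21 x 16
lattice. The network is implemented in the package in plain matrix algebra
(~100 lines) with all randomness drawn from R's RNG, so training is exactly
reproducible under a seed. Hyperparameters beyond the shipped defaults can
be chosen by the reported held-out MSE; we use a plain validation split
rather than a stochastic global search.

*Pitch value* scales the learned surface by goal proximity:
PV(p) = (1 - |p - p_g| / |p_c - p_g|) * fn(ball, p), where p_g is the
attacked goal center and p_c the diagonally opposite corner, the farthest
point of the pitch from the goal (|p_c - p_g| = sqrt(105^2 + 34^2) ≈
110.37 m). PV is 0 at that corner and bounded by the network output
everywhere. *Space quality* is the node-wise product PC * PV: positive
where the attacking team controls ground defenders usually protect.

## Possession features, outcome model, space generation

For a possession with pass timestamps T_k, the origin/destination features
average, over passes, the field sum of space quality weighted by
exp(-lambda * distance to the pass origin/destination) on a 0.5 m grid.
lambda (1/m) controls focus: 0 is the plain field sum, large lambda reads
off the field at the anchor node. The default model-selection grid is
{0.05, 0.1, 0.2, 0.5, 1, 2}. A linear SVM on the standardized features
predicts whether the possession ends in a shot, evaluated by AUC over
repeated random 80/20 splits (default 100 repeats at desk scale; the
original design used 1,000, restored by `n_repeats`). AUC is computed with
a fixed direction so null data calibrates to 0.5 instead of being inflated
by auto-orientation.

*Space generation* of player i at a pass moment is
SG_i = sum over grid nodes and over every other player j of
max(SQ_i - SQ_j, 0), with per-player space quality SQ_i(p) = PI_i(p) * PV(p).
The per-player quantity has no single established definition; we use the
player's own normalized influence weighted by pitch
value, unsigned for both teams, and the sum over j runs over all 21 other
players. SG is nonnegative, zero for a player whose space is matched
everywhere, and invariant under relabeling of uninvolved players.
`aggregate_sg()` credits each pass's receiver SG to the receiver (SG_rec)
and to the passer (SG_pas) — crediting the passer with quality at the
destination instead is a one-line variant isolated in the same function —
reports means per event and per-90 sums, and flags players with fewer than
30 involvements. `pass_network()` summarizes who passes to a focus player
and how much space those passes found.

## The synthetic match generator

Real top-flight tracking is proprietary, so every stage is exercised
against a simulator with plantable ground truth (`simulate_match()`,
`simulate_triplet_corpus()`). What it emulates:

* 2 x (n+1) agents plus ball at 25 Hz, all obeying hard kinematic caps —
  default 8 m/s speed, 4 m/s^2 acceleration, 2 pi rad/s turn rate — at
  every frame (asserted inside the integrator). Players steer toward
  waypoints and brake in proportion to their heading error; without that
  braking a capped-acceleration agent orbits its waypoint at radius
  v^2/a_max instead of reaching it.
* Passes with a plantable duration law Delta = alpha + beta d^gamma + noise
  driven by the passer-receiver distance at initiation — exactly the
  quantity the pass-time regression uses, so with zero noise the planted
  law is recovered to machine precision.
* Defenders chasing a fixed per-player affine function of ball position
  (anchor + gain * ball), projected into their half, plus isotropic noise —
  a function a small network can approximate, which is what makes the
  defensive-influence learnability experiment meaningful.
* Possession outcomes drawn from a logistic law in the final-pass
  receiver's separation, the simulator's stand-in for destination space
  quality.
* Per-player *skill* advances a player's operating zone toward the attacked
  goal and more centrally, while all players seek openness within their
  zone. Skill therefore plants a monotone ordering in expected receiver
  space generation. Two earlier designs are worth recording: scaling a
  player's *separation target* with skill anti-correlates with SG, because
  distance from defenders is distance from learned pitch value; and
  "deeper candidate search" for open spots leaves no recoverable signal,
  because a chosen gap goes stale within a couple of seconds of defender
  drift. Positional advancement is stable across a match, which is why it
  is recoverable.

Deliberate non-realism: no tactical structure, no ball-flight physics
beyond linear interpolation, clearances are single events without animated
ball travel, and attackers re-plan waypoints every 1-2 s. Consequently,
passing tests establishes that the estimators recover what was planted
under the stated conditions — not that the metrics rank real players
correctly, which would require validation against real tracking data and
external outcome metrics.

## Problem sizes and numerical choices

The shipped experiment scales are desk scale, chosen so the full suite
replays in minutes: triplet corpora of 600-5,000 segments (each segment
contributes one endpoint per horizon; the stratified sampler guarantees
n/5 segments per speed bin), 1 m field grids for bulk work and the 0.5 m
grid where the definitions call for it, 200 frames for
defensive-influence training, 100 classifier repeats, and two simulated
matches of 20 minutes for the 20-player skill-recovery experiment.
Other numerical conventions: horizon snapping breaks ties upward; KDE
quadrature checks integrate over the endpoint bounding box padded by six
bandwidths with half-bandwidth spacing; mean shift that drifts outside the
kernel's support simply stops (the mode of an empty neighborhood is
undefined); the SVM experiment redraws degenerate single-class splits and
counts them.

## Known limitations

* Movement models pool all of a player's triplets into one corpus;
  opponent-aware or phase-of-play-conditioned models are out of scope.
* The defensive-influence network sees only (node, ball) coordinates, as in
  the original design; real defensive shape also depends on score, phase
  and personnel.
* Per-player movement models need thousands of triplets per cell before
  their tails are trustworthy; the influence *ratio* is more robust than
  the raw density but still noisy far from the mode.
* Fields are computed per frame with no temporal smoothing.
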
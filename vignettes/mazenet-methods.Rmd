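---
title: "From maze trajectories to behaviour networks: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From maze trajectories to behaviour networks: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mazenet)
```

## The problem

In the Barnes circular maze a mouse on a brightly lit, elevated circular
table learns the location of the single perimeter hole that leads to a dark
escape box, using distal visual cues.  Conventional performance scores —
the number of erroneous hole visits, the latency and the path length to the
target — summarise *how well* an animal performs, but compress away *how*
it searches.  `mazenet` implements a complementary, network-based
description: the animal's stopping behaviour is segmented into discrete
stop episodes, the episodes are clustered into spatial nodes, and the
temporal order of stops defines links between nodes.  Spatial learning then
appears as a systematic simplification of these networks across training —
fewer nodes, fewer links per node, shorter paths — and group differences
can be tested on eight per-trial graph features.

All analyses start from tracked position sequences: one `(t, x, y)` row per
video frame at a nominal 5 Hz, in a 500 × 500-pixel image frame at
2 mm/pixel.  Video tracking itself is out of scope.

## Arena model and coordinate conventions

The arena is described by an `arena_spec()`: centre, arena radius
(default 245 px ≈ 49 cm), 12 holes equally spaced on a ring of radius
200 px (40 cm), and a per-hole *proximity disk* of radius 40 px (about one
mouse body length) used for visit and dwell scoring.  Coordinates follow
the image convention (origin top-left, y down); angles are measured
counterclockwise as seen on screen.

Every trial is rotated rigidly about the arena centre so that its target
hole lies at 45° ("top right"); this canonical frame makes trials and
animals comparable and is an isometry, so distances, speeds and stop
structure are unaffected.  Any fixed canonical angle would do; 45° — the
symmetric top-right diagonal — is used throughout.

Quadrants are bounded by the cardinal axes, so the canonical target sits in
the middle of quadrant 0; placing the target mid-quadrant avoids
classifying boundary grazing near the target as quadrant changes.  A *quadrant cross* is an
excursion through the central zone (disk of radius `0.25 × arena_radius`,
configurable) that exits into a different quadrant than it entered.
This operationalisation follows the contrast the strategy taxonomy draws:
unorganised search involves "many centre crossings", whereas a serial
perimeter run crosses the quadrant boundary *rays* constantly without ever
approaching the centre, so ray crossings cannot be the intended meaning.
The centre-zone radius of a quarter of the arena radius is the
package's choice and is configurable.

## Conventional features

Per trial: the number of errors (visits to dummy-hole proximity disks,
entry events, repeats counted), latency to the first entry of the target
proximity disk, travel distance (sum of successive step norms), per-hole
dwell frames, and block-wise occupancy maps (default 20-px ≈ 4-cm
blocks).  Two readings deserve note:

* **Visits are entry events**, not frames: a visit opens when the animal
  enters a disk from outside and closes when it leaves.  Proximity disks
  are closed (a frame exactly at 40 px is inside).
* **Latency is a geometric proxy.**  Escape-box entry is a hardware event
  invisible in the point sequence; the first target-disk entry is used
  instead and flagged when the target is never reached.

Features are averaged over the three trials of each subject-day
(`daily_average()`) before group statistics.

## Strategy classification

Each training trial gets one label, evaluated in this order:

1. **spatial** — 0 quadrant crosses and fewer than 3 errors;
2. **serial** — fewer than 3 quadrant crosses, hole visits in ring-adjacent
   order, and not spatial;
3. **random** — everything else.

Ring adjacency is modular (hole 11 → hole 0 is adjacent) and direction
reversals are tolerated; a skipped hole breaks seriality.  Both choices are
configurable (`allow_skip`).  Trials with fewer than two distinct visits
are vacuously sequential — such trials are almost always spatial anyway.
Probe trials are not classified: the rules are defined on training trials.

Lift-released animals sit nearly motionless on the lift scaffold for the
first frames; those micromovements would otherwise register as stops and
jitter.  `trim_lift_start()` therefore discards everything before the
first frame farther than 38 px from the centre.  The natural reference
for this radius is the spread of initial positions of hand-released
animals; 38 px is half of a typical 15.25-cm spread at 5 px/cm, and
`manual_start_threshold()` recomputes the threshold from data when MANUAL
trials are available.

## Stop detection and dynamic networks

A sliding window of 5 frames (1 s) qualifies as *stopped* when the path
length inside it is below 20 px (about half a body length).  Taken
literally, a per-window rule would emit a near-duplicate stop every frame
of a long pause; overlapping qualifying windows are therefore merged into
maximal runs, each contributing one stop episode summarised by the centroid
of its frames.  This is the only reading that produces the sparse stop
sets the method is built on.

Stop centroids are clustered by the **City Clustering Algorithm (CCA)**:
points are visited in chronological order; each joins the nearest existing
node if within 20 px of its centroid, otherwise it founds a new node; after
each pass centroids are recomputed as member means and empty nodes dropped;
passes repeat until the partition stabilises (at most 100 passes, with
non-convergence reported).  Chronological pass order and partition
stability as the convergence test are the package's choices.  True
order-independence cannot hold for arbitrary point sets at a fixed
threshold — it is guaranteed, and tested, for well-separated clusters
(inter-cluster gaps above three thresholds).

The per-trial *local network* links every pair of distinct nodes visited by
consecutive stops.  Links are binary and undirected for feature
computation; transition multiplicities are kept for line weights in plots.
Self-transitions are ignored — the networks have no self-loops.  A trial
with no stops yields an order-0 network whose features are `NA`, not zero,
so degenerate trials can be excluded from statistics rather than biasing
them.

## Static (zone) networks

As a criterion-free counterpart, 25 fixed nodes tessellate the arena into
nearest-node zones: 1 at the centre, 8 on a ring at half the arena radius,
16 on a ring at 0.85 of it (rings starting at 45°, so the outer ring
resolves all 12 holes).  This layout is the package's documented choice,
and any 25-point layout can be supplied instead.
Zone adjacency is derived from a 2-px raster of the disk.

A trial becomes the per-frame sequence of nearest nodes (ties to the lowest
id).  Consecutive distinct zones add a link when their cells share a
boundary; when tracking gaps make the animal "jump" across non-adjacent
zones, the straight segment between the two frame positions is decomposed
into the chain of zones it crosses and links are added along the chain.
This preserves the planarity guarantee — every link joins boundary-sharing
zones — without discarding transitions.

## The eight network features

For a binary adjacency matrix `A` with `n` nodes and `m = ΣA/2` links:
number of stops `o`; order `n`; degree `m/n` (note: half the
conventional mean degree — this is the definition this analysis tradition
uses, and comparability with it takes precedence over convention); density `2m/(n(n−1))`; clustering
`C_ws` as the mean over nodes with degree ≥ 2 of `C_i = R_i/(k_i − 1)`,
where the redundancy `R_i` is the average number of links from a neighbour
of `i` to the other neighbours of `i` (algebraically identical to
triangles-over-pairs, which the tests verify to 1e-12); mean unweighted
shortest-path length over reachable unordered pairs (unreachable pairs
excluded and counted); mean betweenness centrality with the standard
fractional weighting `σ_st(i)/g_st` over ordered pairs, unnormalised; and
mean closeness `1/Σd_ij` over reachable targets.

Two ambiguities were settled as follows.  A 0/1 indicator of whether a
node "lies on the shortest path" is ill-defined when several geodesics
tie; the fractional form is standard, coincides with the indicator on
unique-geodesic graphs, and is what Brandes' algorithm computes.  The averaging scope of the
shortest path (ordered vs unordered pairs) is unstated; unordered is used —
for a symmetric graph the two coincide.  Disconnected-pair handling
(exclude and count) is likewise the package's documented choice.

## Global networks

All local nodes of a group-day are pooled and re-clustered with the CCA at
the same 20-px threshold, so every local node belongs to exactly one global
node.  Global links join global nodes supported by at least one local
link, weighted by the number of supporting local links.  Node magnitude is
the natural log of the member count (the log base affects rendering only,
and singletons with `ln 1 = 0` are drawn at a minimum marker size).  The degree-sorted polar
layout places nodes clockwise from 0° (highest degree) to 360° (lowest),
with the five published colour bins on raw degree (white ≥ 12 > yellow ≥ 9
> orange ≥ 6 > red ≥ 3 > brown).

## Group statistics

A thin layer over standard routines: Kruskal–Wallis between groups per day
and Friedman across days within groups, with pairwise Mann–Whitney or sign
tests at the Ryan step-down level `α′ = 2α/(k(m−1))` (the standard
step-down form of Ryan's procedure, with the pair's span `m` taken from
the rank order of group medians).
Effect sizes are `R = |Z|/√N` with the conventional null/small/medium/large
bins.  Undefined feature values are excluded pairwise with counts
reported.  The two-way mixed ANOVA and Tukey HSD used for conventional
features in the original workflow are routine statistics available in base
R (`aov`, `TukeyHSD`) and are not re-wrapped.

## The synthetic trajectory generator

Real animal data for this task are not published, so the package ships a
generator whose defaults *are* the study conditions used by the tests: a
discrete-time correlated random walk at 5 Hz on the default arena, speed
`N(50, 15)` px/s truncated at zero (≈ 10 cm/s), reflecting boundary, and
three archetypes matching the strategy taxonomy:

* **spatial** — steer from the centre straight to the target with small
  heading noise (sd 0.12 rad/step), then settle;
* **serial** — run to a starting hole (default: one slot counterclockwise
  of the target, so the circuit runs the long way round and is
  unambiguously not spatial), then visit ring-adjacent holes to the
  target, dwelling 8 frames at each;
* **random** — free correlated walk (heading noise 0.5 rad/step) with 6
  scheduled traversals through the central zone into a new quadrant,
  emulating the "many centre crossings" of unorganised search.

Stops occur spontaneously at 0.2 episodes/s for a geometric mean of
8 frames, and at every hole dwell.  Stopped positions jitter around a
fixed anchor with marginal sd `stop_threshold/8` = 2.5 px; the jitter is
AR(1) with autocorrelation 0.7 because posture sway and tracking noise are
strongly autocorrelated at 5 Hz — independent per-frame jitter of the same
amplitude would inflate within-window path lengths far above what a
stationary animal produces.  Random-search training trials can end at an
incidental target visit with probability 0.2 per visit, but not during the
first 60 s: naive mice rarely recognise the escape hole immediately, and
these two values put day-1 latencies and errors in the range reported for
naive animals in this task.  Goal-directed trials end when the animal
settles at the target.

`learning_schedule()` encodes acquisition as a per-day mixture of
archetypes whose random share decays geometrically (×0.55/day, reaching 0
on the last day) while the spatial share rises (0, 0.25, 0.45, 0.65, 0.8,
0.9) — rapid early improvement followed by a plateau, the canonical shape
of published learning curves.  `simulate_cohort()` derives per-trial seeds
deterministically from one master seed, so cohorts are byte-identical
across runs.

**What the generator does not emulate:** within-trial learning,
thigmotaxis gradients, speed–turning coupling, tracking dropouts, and
inter-individual variability beyond seed noise.  Passing tests therefore
show that the pipeline recovers planted structure and rule-defined labels
from realistic kinematics — not that it would resolve every phenotype in
real data.

## Numerical choices and degenerate inputs

* Stop windows use a strict `<` threshold; proximity disks are closed.
* Nearest-node ties (static zones, CCA assignment) break to the lowest id /
  first minimum, making every partition deterministic.
* Networks of order 0–1, all-isolated node sets, and never-reached targets
  propagate `NA` markers with reasons rather than zeros.
* The CCA reports non-convergence after 100 passes instead of looping.
* Trajectories shorter than the stop window yield zero stops; trajectories
  with fewer than 2 frames are rejected at construction.

## Problem sizes used by the tests

The oracle suites run 500 random graphs of order ≤ 8 (exhaustive geodesic
enumeration stays cheap), 100 simulated trials each for the stop/CCA,
strategy and planarity suites, and one 19-subject × 6-day × 3-trial cohort
for the learning-curve property; the whole suite completes in about a
minute on one core.  These sizes were chosen to keep exhaustive oracles
exact while matching the original cohort size (n = 19 lift-entry animals)
where it matters statistically.

## Known limitations

* The 25-node static layout and the centre-zone radius are documented
  assumptions, not published values; both are configurable.
* Latency is a proximity proxy for escape; trials where an animal hovers at
  the target without descending will under-report latency relative to a
  hardware event.
* CCA partitions depend on processing order for adversarially spaced
  points at the threshold scale; seed-independence is only guaranteed for
  separated clusters.
* The group-statistics layer implements the nonparametric battery only;
  parametric repeated-measures analyses should use the standard R
  facilities directly.
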
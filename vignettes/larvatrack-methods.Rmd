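---
title: "Tracking and phenotyping individual larvae: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking and phenotyping individual larvae: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(larvatrack)
```

# Scope and model

`larvatrack` follows groups of *Drosophila melanogaster* larvae through
calibrated greyscale image stacks, preserves individual identities across
collisions, and converts the resulting spine time series into a catalogue of
behavioural attributes and group-level analyses. The pipeline has three
phases:

1. **Image processing.** A background model (pixel-wise mean of up to 100
   equidistant frames from the central third of the video) is subtracted
   from every frame; the difference image is thresholded with Otsu's method
   computed on the region of interest, and 8-connected foreground components
   ("blobs") are extracted with their outer contours.
2. **Geometry and the collision graph.** Each blob that may be a single
   larva gets a 200-point contour from periodic cubic smoothing splines, two
   endpoints at the largest curvature maxima, and a 12-point spine built as
   the midline of arc-paired contour points. Blob lifetimes form the nodes
   of a collision graph whose merges and splits record collisions; the
   number of larvae per node is the solution of the integer program
   *minimise* Σxᵢ subject to xᵢ ≥ max(|Pᵢ|, |Cᵢ|, 1) and, at every internal
   node, Σ_{j∈Pᵢ} xⱼ = Σ_{k∈Cᵢ} xₖ. The constraint matrix is totally
   unimodular, so the LP relaxation solved by the package's compact
   two-phase simplex returns integral solutions (asserted to 1e-6).
   Head/tail orientation is decided per subtrack by majority over three
   votes: darker endpoint surroundings, larger distance covered, and net
   motion away from the previous-frame centroid.
3. **Collision resolution.** Ephemeral collisions (two larvae, < 8 s, or a
   brief touch on a larger cluster) are resolved geometrically: each
   participant is a five-link chain (orientation + four joint angles,
   segment lengths and width frozen at entry) fitted per frame by
   brute-force grid search against the residual contour (merged blob minus
   the counterparts' previous-frame silhouettes); on exit, model centroids
   match the nearest outgoing blobs. Longer collisions of two or three
   larvae are resolved statistically: body length, width, area and
   perimeter are z-scored jointly, projected on their first principal
   component, and matched in/out participants are compared by two-sided
   Mann–Whitney U-tests on equal sample sizes (≤ 45 frames adjacent to the
   collision). An assignment wins only when its p-values dominate every
   competing assignment by a factor of 1000. Collisions of four or more
   animals are refused.

The behavioural layer defines: **steps** as strict local maxima of the tail
forward velocity during runs, discarding maxima below 0.6 mm/s; **head
casts (HCs)** as intervals where the head-vector angular speed exceeds
±35 °/s, discarded when the tail-vector angular speed exceeds 45 °/s inside
or when two or more steps fall inside; **runs** as everything outside HCs
plus a 1.5 s margin; **stumble cycles** as inter-step periods with two
interior local minima of the tail forward velocity; and **switches**
between forward and backward crawling from persistent sign changes of the
tail forward velocity.

# Tunable parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `hc_threshold_deg_s` | 35 | °/s | HC detection threshold on HV angular speed |
| `tv_discard_deg_s` | 45 | °/s | TV angular speed discarding a candidate HC |
| `step_min_speed_mm_s` | 0.6 | mm/s | absolute step floor, applied before bl-normalisation |
| `run_exclusion_s` | 1.5 | s | exclusion window around each HC |
| `smooth_window_s` | 0.3 | s | boxcar window for spine positions |
| `ephemeral_max_s` | 8 | s | longest collision given to the shape model |
| `stat_max_frames` | 45 | frames | U-test sample cap per side |
| `stat_margin` | 1000 | — | p-value dominance factor |
| `switch_speed_floor_bl_s` | 0.1 | bl/s | velocity floor for switch detection |
| `switch_persistence_s` | 1.0 | s | persistence for switch detection |

The first six rows are published constants and should not normally be
changed; the switch-detection pair is a declared surrogate (the original
criterion is not described in the source text) chosen so that programmed
backward episodes are recovered at their onset frames.

# The synthetic world

`simulate_track()` generates ground truth directly in the quantities the
detectors measure: the axial (tail-forward) velocity is
v(t) = ±v₀(1 − cos 2πt/T) with period `peristaltic_period_s` and mean
`stride_bl` body lengths per cycle, so the true steps are the analytic
crests; head casts are outward sweeps of the anterior three spine points
about spine point 9 (0.5 s at `hc_amplitude_deg`/0.5 °/s, detected) followed
by a slow 25 °/s relaxation (below threshold) that converts half of the
excursion into a permanent heading change; backward episodes negate the
axial velocity on programmed intervals. Rendering draws each larva as a
tapered capsule (11 segments joining the 12 true spine points, zero width at
the tips) with the anterior third darkened by 40 grey levels — mimicking the
pigmented mouth hooks that make real heads the darker end — on a uniform
background with Gaussian noise, dark-on-light or inverted.

What the generator deliberately does **not** emulate: substrate
deformation, photometric flicker, curling and rolling postures, odour plume
physics (the stimulus is a fixed coordinate), and segment-level peristaltic
waves (the velocity oscillation is imposed on a rigid body). A green test
therefore establishes that the pipeline recovers what it claims from
kinematically faithful but photometrically idealised scenes, not that it is
robust to every artefact of real video.

Defaults are 16 frames/s and 0.1 mm/px, which give a 4 mm larva about
40 px of length (above the 30 px/animal floor the imaging model assumes).
The six-larva benchmark scene (`make_multi_collision_scene()`) runs at
12 frames/s purely to keep its runtime inside the test budget; acquisition
rate is a free parameter of the source material.

# Numerical choices and edge cases

* **Contour smoothing.** The boundary polygon is replicated one chord-length
  period to each side and `smooth.spline` is fitted per coordinate with
  degrees of freedom of half the vertex count, then resampled to 200 points
  equidistant in arc length. Curvature comes from the spline derivatives and
  is normalised convex-positive via the sign of the total turning.
* **Endpoints.** Curvature maxima are plateau-centred (a rounded cap has
  constant curvature, so the raw argmax would sit on the cap edge), must be
  ≥ 30 of 200 positions apart, and require outline elongation
  (principal-axis variance ratio ≥ 1.5) — near-circular blobs, including
  curled larvae, yield an endpoint failure and split the track, consistent
  with treating curled postures as unrecoverable.
* **Plateau maxima** in the step detector count once, at the first frame.
* **Stepping cycles** with zero interior minima are classed as normal.
* **Switch hysteresis.** The peristaltic oscillation crosses zero within
  every cycle, so a naive persistence rule can never fire; an episode
  therefore only ends when the velocity crosses the *opposite* floor.
* **Brightness vote tolerance.** Endpoint brightness differences within two
  grey levels yield no vote (measurement noise is of that order; true head
  darkening is an order of magnitude larger). Full vote ties give
  `head_end = "ambiguous"`.
* **Collision events** are built from *complexes*: connected groups of
  multi-larva nodes plus adjacent single-larva nodes shorter than 0.5 s.
  Grazing contacts flicker at pixel resolution (merge–split chatter at the
  tangency boundary); absorbing sub-half-second fragments into the event
  removes that chatter without touching genuine brief separations.
* **Shape-model search.** The published parameter space is orientation and
  four joint angles; translation is handled by re-anchoring the chain at
  the residual-contour centroid each frame before the grid search
  (orientation ±15° in 3° steps, joints ±20° in 5° steps). With segment
  lengths and width frozen, maximising residual coverage is equivalent to
  maximising intersection-over-union. Residual pixels are subsampled to
  ≤ 150 per frame.
* **Factor-1000 rule for three larvae.** With six candidate bijections,
  every competitor shares one correctly matched pair with the winner, so
  requiring the winner's smallest p-value to exceed the competitor's
  *largest* by 1000 can never be satisfied; three-larva events instead
  require every competitor to be *refuted* — to contain at least one pair
  whose p-value lies a factor 1000 below the winner's weakest pair. The
  two-larva case keeps the literal both-exceed-both rule.
* **Degenerate inputs.** A constant difference image yields an empty mask
  with a degeneracy flag; tracks shorter than the smoothing window yield an
  empty, flagged motion series; a zero-mean or length-<2 sample yields an
  `NA` coefficient of variation.

# Group-level machinery

Tracks shorter than half the video are discarded before cohort analyses
(exactly half is kept: the weakest exclusion that still guarantees at most
one track per physical animal). The random forest is a CART/Gini,
bootstrap-bagged, `sqrt(p)`-feature-subsampling implementation built into
the package (no suitable forest implementation is available in the target
environment), evaluated by five-fold cross-validation repeated three times
with reshuffling; accuracy is the unweighted mean of per-class correct
rates from the pooled out-of-fold confusion matrix, importance is mean
decrease in impurity, and importance ranks are averaged over ten complete
repetitions. Forest size (500 trees) and the impurity importance metric are
config-pinned choices; everything is reproducible bit-for-bit from one
integer seed. The nonparametric battery (Kruskal–Wallis with Mann–Whitney
post-hocs gated on omnibus significance, Wilcoxon signed-rank, Spearman
correlation) is two-tailed throughout with Bonferroni–Holm adjustment
within each declared family.

# Known limitations

* MP4/compressed video input is out of reach in the target environment;
  frames are accepted in memory, as generator functions, or as PGM/PNG
  stacks on disk.
* Identity recovery across the region-of-interest boundary is available as
  the exported asymmetric re-identification routine but is not wired into
  the scene orchestrator (the benchmark scenes keep all animals inside the
  arena).
* Behaviour *within* collisions is not scored, and curled postures are not
  recovered — both deliberate scope boundaries of the tracking model.
* The generator's `hc_angle_deg` is the head-vector excursion of the
  programmed sweep; the *measured* HC angle is a bending-angle change and
  is geometrically smaller. Tests therefore compare HC counts and sides,
  not amplitudes, against ground truth.
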
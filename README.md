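# larvatrack

Individual-level tracking and behavioural phenotyping of *Drosophila
melanogaster* larvae crawling in groups.

Studying how *individual* larvae behave — rather than group averages —
requires following each animal through an entire recording, including the
moments when animals crawl over each other and ordinary trackers lose their
identities. `larvatrack` implements a complete pipeline for that problem:

* **Segmentation** — background model from the central third of the video,
  Otsu thresholding on the difference image, 8-connected blob extraction.
* **Larva geometry** — 200-point smoothing-spline contours, endpoint
  detection from curvature maxima, a 12-point spine (tail tip to head tip),
  body length, width, area and perimeter per frame.
* **Collision graph** — blob lifetimes as nodes, merges/splits as edges;
  the larva count per node solves the integer program
  min Σxᵢ s.t. xᵢ ≥ max(|Pᵢ|,|Cᵢ|,1) and Σ_{j∈Pᵢ}xⱼ = Σ_{k∈Cᵢ}xₖ at
  internal nodes (totally unimodular, solved as an LP).
* **Collision resolution** — a five-link shape model fitted by grid search
  over orientation and four joint angles for ephemeral two-larva contacts
  (< 8 s); statistical re-identification (PCA over body length, width,
  area, perimeter; Mann–Whitney U-tests on ≤ 45 frames; factor-1000
  p-value dominance) for longer collisions of two or three larvae;
  collisions of four or more are refused.
* **Behavioural events** — peristaltic steps (local maxima of tail forward
  velocity ≥ 0.6 mm/s during runs), lateral head casts (HV angular speed
  beyond ±35 °/s with tail-quiet and single-step discard rules), run
  phases (1.5 s exclusion around HCs), stumble cycles (two interior
  velocity minima), forward/backward switches.
* **Attributes** — the 30 random-forest attributes (bending, angular
  speeds/accelerations, inter-step and head-cast statistics with
  within-individual CVs, forward velocities, distances), mm/body-length
  variants, odour-related measures, Δ-values, peak values, 2 s binned
  series.
* **Cohort statistics** — half-video track filter, seeded CART random
  forest with 5-fold × 3 cross-validation and mean-of-class-rates
  accuracy, impurity-importance ranks over 10 repetitions, and a
  Kruskal–Wallis / Mann–Whitney / Wilcoxon / Spearman battery with
  Bonferroni–Holm correction.
* **Synthetic scenes** — a deterministic kinematic simulator plus renderer
  with frame-level ground truth (spines, step times, HC intervals,
  collision events, switches), so the entire pipeline is testable without
  real videos.

## Worked example

Two simulated larvae cross paths for about six seconds; the tracker merges
their blobs, resolves the collision with the shape model, and restores both
identities:

```r
library(larvatrack)

scene <- make_collision_scenario("ephemeral_2", seed = 1)
state <- track_pipeline(scene, track_config())
with_res <- finalize_tracks(state, "full")
with_res
#> <larva_tracking> 2 records, 1 collision events (1 resolved), long-track fraction 1.000

match_records_to_truth(with_res, scene)
#>   record gt_id purity covered_frames
#> 1      1     2      1            392
#> 2      2     1      1            392

finalize_tracks(state, "none")$stats$frac_frames_in_long_tracks
#> [1] 0
```

Each record covers the full 30 s video (purity 1 = every frame matched to
the same true animal); with resolution disabled the same video fragments
into four short tracks, none reaching half the video.

Event detection and attributes on a simulated single larva:

```r
p  <- larva_params(peristaltic_period_s = 1, hc_rate_hz = 0.1,
                   hc_amplitude_deg = 40, rng_seed = 11)
gt <- simulate_track(p, duration_s = 60, fps = 16, start_mm = c(0, 0))
ev <- detect_events(as_track_record(gt))
c(steps = nrow(ev$steps), hcs = nrow(ev$hcs),
  is_interval = mean(ev$cycles$interval_s))
#>       steps         hcs is_interval
#>  47.0000000   4.0000000   0.9985119
```

The mean inter-step interval recovers the programmed 1 s peristaltic
period; all 4 programmed head casts are detected (steps inside the 1.5 s
HC exclusion windows are, by definition, not counted).

## Command line

```sh
Rscript inst/cli/larvatrack-cli.R simulate --scenario ephemeral_2 --seed 1 --out scene/
Rscript inst/cli/larvatrack-cli.R track --frames scene/ --fps 16 --mm-per-px 0.1 --out-dir out/
Rscript inst/cli/larvatrack-cli.R classify --table cohort.csv --label-col label --seed 1
```

`track` writes per-larva spine and attribute CSVs plus a JSON tracking
report (collision events, resolution outcomes, fraction of data in long
tracks).

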
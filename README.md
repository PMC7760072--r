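# stalltrack

Quality control, validation metrics and behaviour analytics for keypoint
trajectories of stabled horses.

Markerless pose trackers turn stall videos into per-frame pixel positions
of a few anatomical keypoints — here nose, withers and tail — but the raw
tracks are noisy: the detector drops out when lighting is poor or people
stand in the stall, and it teleports onto static lookalikes (automatic
waterers, manure piles, shoes) hundreds of pixels from the horse.
`stalltrack` is for researchers who have such trajectory tables (time-lapse
footage, nominally 2 images per second at 2.7K) and want to (i) screen them
for mislabels, (ii) score detection quality against annotated ground truth,
and (iii) derive behaviour read-outs — occupancy maps, time budgets, a
weight-shifting signature relevant to post-surgical pain monitoring.

## What it computes

**Mislabel screening.** For successive predicted frames the jump statistic

    S = ((x2 - x1) * (f2 - f1))^2 + ((y2 - y1) * (f2 - f1))^2

is reported, and a pair is flagged when its Euclidean displacement exceeds
200 px between consecutive frames (scaled to `g * 200` px over a prediction
gap of `g` frames). Runs of more than 30 consecutive images where a visible
marker has no prediction are flagged as missing runs. Flagged frames feed a
wrongly-predicted count WP per marker; PM/TI (predicted images over total
images) and %WP = 100·WP/PM summarise per-video robustness.

**Validation.** Per-frame confusion classification against annotated
visibility (TP: prediction within a match radius of a visible marker; TN:
hidden marker correctly unpredicted; FP: mislabelled or predicted though
hidden; FN: visible but unpredicted), over the first and last 1000 images
of each video, then

    sensitivity = TP / (TP + FN)
    error rate  = FP / (TP + FP)
    accuracy    = (TP + TN) / (TP + FP + TN + FN)

with paired t-tests comparing model versions and one-way ANOVA comparing
markers.

**Behaviour analytics.** Position heat maps, polygonal time-in-region
budgets, x/y series aligned with behaviour labels, rolling y-variance with
a weight-shifting detector for rest periods, a rule-based classifier for
the four-class ethogram (standing observation, rest, feeding, moving), and
behaviour time budgets in minutes and percent.

**Synthetic stall scenarios.** Because the original hospital videos are not
distributable, a seeded simulator generates ground-truth tracks from a
four-state behaviour Markov chain with per-state kinematics, schedules tail
occlusion while the horse faces the door, and degrades the truth with
jitter, dropout runs and teleport mislabels — logging every injected event
so recovery can be scored exactly.

## Worked example

```r
library(stalltrack)

sc  <- build_scenario(n_frames = 28800, seed = 1)   # 4 h at 2 img/s
sim <- simulate_tracks(sc)
deg <- degrade_to_predictions(sim$ground_truth, sc$artifacts, sc$geometry, seed = 2)

# screen for teleports and missing runs
qc <- qc_report(deg$tracks, sim$ground_truth)
qc$wp
#>    marker  WP
#> 1    nose 102
#> 2 withers  84
#> 3    tail  78

# score the nose detections over the first 1000 images
cc <- classify_confusion(deg$tracks$nose, sim$ground_truth, 100, 1:1000)
cc
#> Confusion (nose, custom): TP 953  TN 0  FP 3  FN 44
unlist(performance_metrics(cc))
#> sensitivity  error_rate    accuracy
#> 0.955867603 0.003138075 0.953000000

# classify behaviour from the tracks and compare with the generator's labels
pred <- classify_behaviour(deg$tracks)
mean(pred$behaviour == sim$labels$behaviour)
#> [1] 0.9331597

behaviour_time_budget(sim$labels, sc$fps_tlv)
#>                    key frames   minutes  percent
#> 1 standing_observation  12217 101.80833 42.42014
#> 2                 rest   5804  48.36667 20.15278
#> 3              feeding   7262  60.51667 25.21528
#> 4               moving   3517  29.30833 12.21181
```

The QC table says 78–102 frames per marker sit in jump segments (the
injected teleports plus their neighbour frames, deduplicated); sensitivity
0.956 means 44 of 997 visible nose frames went unpredicted in dropout
runs; and the rule cascade recovers 93.3% of the simulated behaviour
labels, so four-hour time budgets like the one shown are trustworthy to a
few percentage points under these artifact rates.

## Command line

A thin CLI over the same functions lives at `inst/scripts/stalltrack.R`
(subcommands `simulate`, `qc`, `validate`, `case-study`, `all`), driven by
a YAML run config.
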
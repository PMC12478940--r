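# hatchwatch

Identity-preserving tracking and circadian analysis of *Drosophila
melanogaster* development from per-frame object detections.

Automated monitoring of standard rearing vials produces, every few
minutes, a list of detected objects — wandering third-instar larvae, full
pupae, empty pupae, adult flies — as bounding boxes with class labels.
hatchwatch turns such a detection stream into biology: continuous
per-specimen trajectories, pupation and eclosion time points, and an
estimate of the circadian eclosion rhythm. It is written for fly labs
running long-term developmental or chronobiology experiments (eclosion
monitoring of clock mutants, development timing during routine rearing)
and for anyone who needs a tested, self-contained reference implementation
of this tracking-by-detection pipeline.

## What it computes

**Tracking.** Detections in consecutive frames are associated by
bounding-box overlap. For boxes $b_i, b_j$ the score is the Jaccard index

$$J(b_i,b_j) = \frac{|b_i \cap b_j|}{|b_i \cup b_j|},$$

and a pair is admissible when $J > 0.6$ and the developmental stages are
the same or adjacent (larva – full pupa – empty pupa; adults found new
tracks). The $m \times n$ score matrix is augmented with $n$ dummy rows
and $m$ columns (zero-scored, so anything may stay unmatched; the
dummy–dummy block is zero) and solved as a maximum-weight Hungarian
assignment. Tracks missing for up to 3 frames are bridged with their last
observed box; tracks below 30 frames are discarded; stage sequences are
median-filtered (window 5) on the ordinal larva < full pupa < empty pupa
< adult scale.

**Events.** A sliding window of $\tau = 7$ frames marks the earliest time
point where at least 4 of the next 7 frames are full pupa (pupation) or
empty pupa (eclosion) — at a 10-minute frame interval this is at most 30
minutes before the visible transition, never after it.

**Rhythm.** Eclosion events are binned into 2-hour slices and the
classical variance-normalized Lomb-Scargle periodogram is evaluated on a
14–34 h period grid; the peak period and an analytic significance
estimate are reported.

**Simulation.** A seeded synthetic colony generator (raised-cosine
inhomogeneous Poisson eclosion times, stationary pupae, untrackably fast
adults, detector-style class-confusion noise) reproduces the full study
conditions — 50 animals, 3 vials, 14 days at 10-minute frames — so the
entire pipeline is testable without hardware. Presets encode wild-type
(`iso31`, 24 h), `per_short` (19 h), `per_long` (28.3 h) and arrhythmic
(`per0`) phenotypes.

## Worked example

```r
library(hatchwatch)

# a full 14-day colony with detector-level noise
sim  <- simulate_colony(rhythm_preset("iso31"), seed = 42)
dets <- corrupt_detections(sim, noise_model("detector"), seed = 43)

summary <- run_pipeline(dets)
summary
#> <pipeline_summary>
#>   detections: 108369   tracks kept: 52
#>   pupation events: 46   eclosion events: 50
#>   rhythm peak: 24.00 h (p = 0.00465)

glance(summary$periodogram)
#> # A tibble: 1 × 5
#>   peak_period_h peak_power p_value n_obs m_indep
#>           <dbl>      <dbl>   <dbl> <int>   <dbl>
#> 1            24       8.20 0.00465   120      17
```

Reading: 108,369 noisy detections over 2016 frames collapse to 52 kept
trajectories for the 50 simulated specimens (noise occasionally splits
one). All 50 eclosions are recovered; 46 pupations (tracks first seen
already pupated yield none). The periodogram peaks at 24.0 h — the
wild-type circadian period the `iso31` preset encodes — and the peak is
significant ($p \approx 0.005$). `autoplot(summary$periodogram)` draws
the periodogram, `plot_event_series(bin_events(summary$events))` the
binned event counts, `plot_stage_timelines(summary$tracks)` the
per-track stage ribbons.

Individual stages are plain functions over tibbles and compose with the
pipe:

```r
tracks <- read_detections("run.jsonl", "jsonl") |>
  track_detections() |>
  smooth_stages() |>
  filter_short_tracks()
events <- collect_events(tracks, event_type = "eclosion")
estimate_rhythm(events)
```

A thin command-line front end is installed as `exec/hatchtrack`
(`hatchtrack simulate | track | events | rhythm | run`).

## Package layout

- `R/stages.R`, `R/config.R` — stage labels, adjacency, configuration
- `R/matching.R`, `R/tracker.R` — IoU, augmented assignment, tracking
- `R/postprocess.R` — smoothing, filtering, event extraction
- `R/rhythm.R` — binning, Lomb-Scargle, rhythm estimation
- `R/synthetic.R` — colony simulator, noise model, frame renderer
- `R/detections-io.R`, `R/vials.R`, `R/store.R` — formats, calibration,
  persistence, pipeline
- `vignettes/methods.Rmd` — the model, its assumptions, design decisions
  and known limitations
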
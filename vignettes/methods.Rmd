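---
title: "Tracking Drosophila development and eclosion rhythms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking Drosophila development and eclosion rhythms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hatchwatch)
```

## The problem

Long-term monitoring of *Drosophila melanogaster* rearing vials produces a
detection stream: for every frame (typically one every 10 minutes over one
to several weeks), an object detector reports bounding boxes classified as
wandering third-instar larva, full (filled) pupa, empty pupa, adult fly, or
an out-of-focus object on the far side of the vial. Three questions drive
the analysis:

1. Which detections across frames belong to the *same* specimen
   (identity-preserving tracking)?
2. When did each specimen pupariate and eclose (event extraction)?
3. Do the eclosion times carry a circadian rhythm, and with what period
   (periodogram analysis)?

hatchwatch implements the full chain after the detector, plus a synthetic
colony generator so every stage can be exercised and validated without
imaging hardware.

## Tracking model

At a 10-minute frame interval larvae move slowly and pupae not at all, so
spatial overlap is a sufficient association cue: no appearance features and
no motion model are used. For candidate track $i$ (represented by its last
observed box $b_i$ and stage) and detection $j$ the score is the
intersection-over-union $J(b_i, b_j) = |b_i \cap b_j| / |b_i \cup b_j|$.
A pair is *admissible* when $J > 0.6$ (strictly more than 60% overlap) and
the two stages are the same or adjacent on the developmental chain
larva – full pupa – empty pupa. Adults are adjacent only to themselves: an
eclosing adult is a new free-moving object, not the continuation of the
pupal case it leaves behind, so it founds a new track. The relation is kept
symmetric because single-frame misclassifications can transiently "reverse"
a stage; median smoothing repairs those afterwards.

With $m$ candidates and $n$ detections, scores form an $m \times n$ matrix
augmented by $n$ dummy rows and $m$ dummy columns to an
$(m+n)\times(n+m)$ matrix, so that every track and every detection can
also be left unmatched. Dummy entries are 0, the dummy–dummy block is 0,
and inadmissible real pairs are assigned a negative sentinel
(`FORBIDDEN = -1`). A maximum-total-score perfect matching of this matrix
(Hungarian assignment) then links exactly those pairs that beat leaving
both sides unmatched: any admissible pair scores above 0.6 and therefore
above the dummy alternative, while no negative entry can ever enter an
optimum. This formulation realizes the overlap gate exactly under
maximization; note that plugging a dummy value of 1 into a maximization
objective would instead dominate every IoU and match nothing, so the
sentinel/zero convention is the coherent reading of the gate.

The solver is an $O(k^3)$ potentials-based shortest-augmenting-path
assignment algorithm, run after splitting the admissible bipartite graph
into connected components (stationary pupae give components of size one,
so the cubic cost is paid only where boxes actually contend). Ties between
equal-total matchings are broken by the solver's fixed insertion order —
deterministic, which is the property that matters for reproducibility.
A brute-force enumeration oracle checks optimality for all $m, n \le 6$
in the test suite.

### Gaps and track lifecycle

Occasional missed detections must not split identities. Candidates for
frame $t$ are all tracks last observed at $t-1$ through $t-4$
(`max_gap_frames = 4`); a re-observed track has the skipped frames filled
with its last observed box and stage, flagged `observed = FALSE`. The held
box is not extrapolated: at this sampling rate larvae barely move and
pupae are stationary, so a "hold" model introduces less error than any
motion estimate. Tracks unobserved for 4 consecutive frames are closed and
never reopened. Unmatched detections of tracked classes found new tracks
immediately; the spurious short tracks this creates (mostly from adults,
which move far too fast to be tracked at 10-minute intervals) are removed
by the final length filter: tracks covering fewer than 30 frames
(`min_track_length = 30`, gap-filled frames count) are discarded.

## Stage smoothing and event extraction

Each track's stage sequence is median-filtered on the ordinal scale
larva = 0 < full pupa = 1 < empty pupa = 2 < adult = 3 with a centered
window of 5 frames. The median of an odd window is always one of its
members, so smoothing never invents a stage; isolated misclassifications
vanish while true transitions (runs longer than half the window) stay in
place. The first and last 2 frames of a track keep their raw labels rather
than shrinking the window — the simplest defensible edge rule, affecting
at most 2 frames per end (`stats::runmed`'s `endrule = "keep"` implements
exactly this). Adult is placed *above* empty pupa on the ordinal scale so
pupal/adult confusions cannot collapse into the larval range. Smoothing
runs after gap filling, so the filter always sees a gapless sequence.

Events are marked with a sliding majority window of $\tau = 7$ frames: the
*earliest* time point $t$ such that at least $\lceil\tau/2\rceil = 4$ of
the frames $t, \dots, t+6$ carry the full-pupa class is the pupation time;
the analogous earliest empty-pupa majority is the eclosion time. Windows
that would run past the end of the track are not evaluated. Two
consequences are worth stating plainly:

* The rule fires up to $\lfloor\tau/2\rfloor = 3$ frames (30 minutes)
  *before* the visible transition and never after it. On noise-free
  simulations the offset is exactly $-3$ frames. This early bias is
  inherent to the literal majority rule and is documented rather than
  corrected, so that event times remain comparable with other
  implementations of the same rule.
* Pupation additionally requires an earlier frame with a different label —
  a track first seen as a full pupa was already pupated, and reporting a
  pupation for it would be an artifact. Eclosion needs no such guard (the
  earliest empty-pupa majority is unique). If a noisy sequence produces a
  pupation window *after* the eclosion point, the pupation record is
  dropped to preserve developmental order. Pupation timing is inherently
  less sharp than eclosion timing, since pupariation is gradual while
  eclosion flips a pupa to an empty case between two frames.

## Rhythm analysis

Eclosion events are aggregated into 2-hour slices (half-open bins) and the
classical normalized Lomb-Scargle periodogram is computed on the bin
centers after mean subtraction, with the standard per-frequency phase
offset $\tau_\omega$ that orthogonalizes the sine and cosine terms, and
normalization by the sample variance. Power is then invariant under
adding a constant to all counts and under positive rescaling. The test
grid is 14–34 h in 0.1 h steps, bracketing the circadian periods of
interest (about 19 h for *per*-short mutants, 24 h for wild type, 28 h for
*per*-long). `estimate_rhythm()` bins from the first event (snapped down
to the bin grid) through the last: eclosion only begins around day 4–5
once the first animals complete development, and including the empty
pre-onset stretch would inject a step artifact rather than rhythm signal.
Binning at 2 h matches the conventional actogram-style aggregation; the
periodogram is deliberately computed on the binned series, not raw event
times, so its input is exactly what the event plots display.

Peak significance uses the standard analytic null for the maximum of an
exponential-distributed periodogram, $p = 1-(1-e^{-z})^M$, with the
number of independent frequencies approximated as $M = \text{span} /
\min(\text{period grid})$. This is a conservative approximation (the grid
spans fewer truly independent frequencies than $M$), adequate for the
rhythmic/arrhythmic distinction it serves here; it is not an exact
false-alarm probability. A constant series is reported with zero power
everywhere and $p = 1$.

The relevant resolution scale for period recovery is the spectral
resolution element $P^2/T$ (the period change that shifts the frequency by
one independent step over a record of length $T$): about 1.7 h at 24 h,
2.4 h at 28.3 h and 1.1 h at 19 h for a 14-day record. Recovery tests and
the acceptance script use exactly this tolerance, with the median over 20
seeded simulations.

## The synthetic colony

The generator's defaults *are* the study conditions used throughout the
tests: 50 animals across 3 vials, 14 days (336 h) at one frame per 10
minutes (2016 frames). Eclosion times follow a raised-cosine
inhomogeneous Poisson process,
$\lambda(t) = r\,(1 + A\cos 2\pi (t-\phi)/P)$ for $t$ past a development
onset, sampled by thinning — the simplest process with a controllable
period and amplitude. Presets encode the four phenotypes: `iso31`
($P = 24$ h), `per_short` ($P = 19$ h), `per_long` ($P = 28.3$ h, onset
delayed by a day, reflecting the slower development of this genotype),
`per0` ($A = 0$). Shared defaults: amplitude 0.8, baseline 0.5 events/h,
onset 96 h (eclosion begins around day 4), pupal duration 96 h, larval
wandering visible for the final 24 h before pupariation (earlier instars
stay in the food and are not modeled).

Geometry is calibrated to a realistic pixel scale: a 3900 × 2800 frame
(three ~1300 px vial strips, the scale a 12-megapixel sensor yields for
three 41.5 mm vials), pupal boxes 100 × 44 px, larvae 92 × 36 px, adults
110 × 50 px. Larvae perform a mean-reverting bounded-step walk around
their pupation site (displacement bounded by ±18/±12 px, per-step change
bounded so that consecutive-frame IoU always exceeds the 0.6 gate by
construction), descend onto the site over the last 10 larval frames, and
the concentric larva-to-pupa box change alone has IoU 0.75. Pupation
sites are rejection-sampled at least 150 px apart, which makes
cross-specimen IoU above the gate geometrically impossible — identity
preservation on noise-free scenes is therefore a designed property of the
study conditions, and the tracking tests verify the tracker achieves it
rather than gamble on favorable seeds. Adults teleport to a uniform vial
position every frame, mirroring the fact that flying adults cannot be
tracked at this frame rate.

The noise model resamples each detection's class from a per-class
confusion row (defaults follow published per-class detector accuracies
for this kind of backlit vial imagery: 95%/97% for full/empty pupae, 86%
for adults with 12% to out-of-focus, 84% for larvae with 8% to full
pupae; unreported off-diagonal mass goes to out-of-focus/background),
jitters box corners with 1 px Gaussian noise, and adds ~2 spurious
out-of-focus boxes per frame. A `background` outcome drops the detection.

What the simulator does *not* emulate — and hence what passing tests do
not certify about real recordings: occlusions and clutter at the food
interface, larvae crossing each other at close range, out-of-focus
*trackable* animals on the far vial wall, detector failure modes that are
correlated over time rather than frame-independent, condensation and
lighting drift, and vials so crowded that pupation sites genuinely abut.
On real data those effects can fragment tracks or merge identities in
ways the synthetic benchmark cannot reveal.

## Degenerate inputs and numerical choices

* Empty frames, empty files and zero-track experiments flow through every
  stage and produce valid empty outputs.
* Boxes are continuous pixel rectangles, origin top-left; degenerate
  (zero-area) boxes are rejected at the IoU layer.
* Detections on a vial boundary go to the lower vial id (deterministic
  tie-break); detections outside every ROI are dropped.
* Vial calibration binarizes with a two-class intensity split (1-D
  2-means, the minimum within-class-variance threshold), smooths the
  column-wise foreground fraction with a running mean about 2% of the
  image width wide, and takes up to three plateaus above half the peak
  density, discarding slivers narrower than 5% of the image. A uniform
  image is an error that advises the manual ROI override.
* Results persist to a versioned, self-describing JSON container
  (column-oriented per track; full numeric precision, so reload equals
  save exactly), with CSV export of events and periodograms for
  downstream chronobiology tooling. The layout mirrors the logical
  grouping meta / tracks / events / sensors.
* All randomness in the synthetic module flows through explicit seeds;
  the analysis pipeline itself is deterministic, and repeated runs on the
  same inputs produce byte-identical stores apart from the creation
  timestamp.

## Problem sizes used in the tests

The full-scale fixtures run the complete study conditions (50 animals,
2016 frames, tracked twice: noise-free and with detector noise); rhythm
recovery uses 20 seeded event streams per preset and the arrhythmicity
check 100; the assignment oracle checks 500 random matrices with up to 6
tracks and 6 detections; unit tests use a compressed 6-animal, 360-frame
colony. These sizes keep the whole suite comfortably within a couple of
minutes on a single core while still exercising every code path at the
scale the defaults describe.

## Known limitations

* Event times inherit the documented $\le 3$-frame early bias of the
  majority rule.
* The significance estimate for the periodogram peak is approximate (see
  above); for publication-grade rhythm statistics, export the binned
  series and use a dedicated chronobiology package.
* The tracker holds the last box across gaps instead of extrapolating;
  fast larvae at higher frame rates would warrant a motion model.
* Closed tracks are never reopened: a specimen occluded for more than 4
  frames returns as a new identity and the two pieces are not re-linked.
* Pupation timing is intrinsically softer than eclosion timing; treat
  pupation events as indicative, not sharp.
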
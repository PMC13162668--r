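---
title: "penwatch: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{penwatch: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

penwatch infers what group-housed pigs are doing from nothing more than
the bounding boxes an object detector draws around them, and relates that
to the thermal environment of the pen. This vignette is the package's own
account of the science: the models, their assumptions, every tunable
parameter that matters, what the synthetic data emulate (and what they do
not), and the numerical and design decisions taken where the problem was
genuinely open.

## 1. From boxes to behaviors

The detector emits, per video frame, normalized boxes
`class_id c_x c_y w h [conf]` in a two-class scheme — *lying* or
*standing* — because postures are what a detector can learn reliably from
overhead/oblique pen views. Eating and drinking are not detector classes:
they are standing postures in particular places, so they are recovered
geometrically.

The pen geometry is a set of axis-aligned pixel rectangles with roles
*feeder*, *drinker*, or *inactive_feeder* (an unused feeder that should
never produce eating but is a known magnet for false detections, its color
resembling the animals). For a zone $Z$ and the standing boxes $B_i$ of a
frame, occupancy is

$$\mathrm{OC}(Z) \;=\; \frac{\left|\bigcup_i (B_i \cap Z)\right|}{|Z|} \in [0,1],$$

computed exactly by a slab sweep over rectangle edges (union semantics:
overlapping or duplicated boxes are not double counted). A standing box is
reclassified as **eating** when the feeder meets the occupancy rule *and*
the frame lies in a feeding window, as **drinking** when the drinker meets
it (any time of day); lying boxes are never reclassified — a pig lying
against the drinker is resting, not drinking.

Assumptions worth stating plainly:

* **No identity tracking.** Counts are per frame; budgets are
  animal-hours summed over whoever was detected, exactly as a frame-wise
  detector provides. Per-animal budgets are out of scope.
* **The occupancy rule is ambiguous in prose** ("occupied in at least 50%
  of the rectangle"). The default reads the denominator as the *zone* (the
  form of the OC equation above): the zone must be half covered, and every
  standing box intersecting it then shares the behavior. A per-detection
  alternative (`rule = "detection"`: at least half of the *box* inside the
  zone) is selectable; it is stricter for small animals in large zones and
  looser for large boxes grazing small zones.
* A box meeting the rule for both a feeder and a drinker is assigned to
  the zone with the larger per-box overlap fraction, ties to the drinker:
  drinking bouts are rare and brief, so losing one costs more than losing
  a moment of eating.
* **No temporal smoothing.** A box that lingers over the drinker after the
  pig stopped swallowing still counts as drinking — the known over-count
  mechanism of frame-wise inference; a minimum-event-length filter was
  deliberately left out of the default path to keep the frame-count
  semantics exact.

## 2. Time budgets

Durations use the *camera's* native rate: $\text{hours} =
\text{frames}/(\mathrm{FPS}\cdot 3600)$. The model-throughput rate
$\mathrm{FPS} = 1000/(t_p + t_i + t_{nms})$ (pre-processing, inference,
non-maximum suppression, in ms per frame) is computed and reported by
`fps_from_timings()`, but it measures how fast the detector ran, not how
long a behavior lasted; conflating the two changes every duration by the
ratio of the rates. Budget percentages divide by the four-behavior total
and are reported to 2 decimals (hours to 4), the convention of the
validation tables this package mirrors.

## 3. Thermal comfort

Dew point uses the Magnus form with $b = 238.88$ °C and $c = 17.368$:
$$\gamma(T, RH) = \ln(RH/100) + \frac{cT}{b+T}, \qquad
  \mathrm{DPT} = \frac{b\,\gamma}{c - \gamma}.$$
This is the only reading of the constants under which saturation forces
$\mathrm{DPT} = T$ — the identity the test suite checks to $10^{-9}$ °C —
and it is monotone in both arguments. RH is required in (0, 100]: a dew
point of perfectly dry air is undefined, and the function refuses rather
than extrapolates.

The black globe humidity index is the affine
$\mathrm{BGHI} = \mathrm{BGT} + 0.36\,\mathrm{DPT} + 41.5$, classified for
pigs as stress $\le 67$ < comfort $\le 74$ < alert $\le 76$ < emergency.
The published class table leaves the intervals (67, 68] and (74, 75]
uncovered; penwatch closes the gaps by treating the bounds as contiguous
half-open intervals (upper bound inclusive), matching the accompanying
prose ("between 68 and 74 … between 74 and 76 … exceeds 76"). Physiology
is *normal* when RT ≤ 39.3 °C **and** RR ≤ 60 mov·min⁻¹, heat stress when
either bound is exceeded; all boundary comparisons are inclusive on the
safe side. Air-temperature bands are per production phase (growth: optimal
18–21 °C, recommended 8–30 °C; termination: 15–18 and 5–27 °C). For
humidity two published bound sets disagree (a "good 70" column versus a
50–70% prose range); the default is the prose range [50, 70] with critical
below 40 or above 90, and all of these live in `comfort_thresholds()`,
not in code.

## 4. Detection evaluation

Matching is greedy: within each frame and class, predictions in order of
descending confidence consume the unmatched truth with the best IoU at or
above the threshold (default 0.5). Greedy-by-confidence is the convention
of detector benchmarks; on every random small instance the test suite
compares it against an exhaustive optimal assignment. Average precision
integrates the monotone precision envelope over recall (all-points
interpolation, the YOLO-ecosystem convention; a 101-point mode is
selectable), mAP50-95 averages IoU thresholds 0.50:0.05:0.95, and the
"Average" rows of reports are unweighted class means — the convention that
reproduces the published benchmark tables' average rows from their
per-class entries. Degenerate 0/0 precision or recall is reported as 0
with a `degenerate` attribute rather than NaN, so downstream report
arithmetic never propagates missing values silently. Duration agreement
uses MAE, RMSE (MAE ≤ RMSE always; equality iff all errors are equal in
magnitude) and $R^2 = 1 - SS_{res}/SS_{tot}$, which is NA with a warning
when the truth is constant.

## 5. The synthetic barn

The simulator generates everything the pipeline consumes, for two thermal
regimes emulating the study conditions:

| parameter | cooled | uncooled | why |
|---|---|---|---|
| mean T (°C) | 22.59 | 30.43 | regime means of the observed stalls |
| T amplitude (°C) | 1.9 | 4.4 | reproduces the observed min–max span |
| mean RH (%) | 81.99 | 54.62 | observed means; RH runs in anti-phase with T |
| radiant offset (°C) | +0.391 | +0.597 | makes the series' mean BGHI equal the observed stall means (71.45 / 79.82) given mean T and RH |
| peak hour | 14:00 | 14:00 | afternoon maximum, morning minimum |
| n pigs | 3 | 3 | pen stocking of the study |
| p_miss | 0.05 | 0.16 | occlusion/low-light misses; detection is harder in the uncooled stalls (overlapping animals, darker wet floor) |
| box jitter (px) | 2 | 2 | localisation noise |
| p_fp per frame | 0.01 | 0.01 | spurious standing box at the unused feeder |
| confidence | Beta(18,1) lying, Beta(14,1) standing | same | detector probabilities concentrated near 0.9–1 |

Behavior follows a first-order Markov chain per pig at 1 s resolution
(held for `fps` frames when rendering), with the transition matrix
switched by thermal state: the *comfort* matrix applies while BGHI ≤ 74,
the *heat* matrix above. The matrices are calibrated — a fixed-point
adjustment of jump-destination weights at chosen mean dwell times (lying
120 s, standing 30 s, eating 60 s, drinking 15 s comfort / 20 s heat) —
so that their stationary distributions equal the regime budget fractions
of detected time (comfort .680/.200/.115/.004; heat .697/.168/.123/.012):
heat-stressed pigs lie slightly more, explore less, and drink about three
times as long. Eating is additionally gated by the feeding schedule
(default: feed distributed at 08:00 and 15:00 and available for about
five hours after each); a proposed eating state outside a window becomes
standing, since the feeder is empty then.

Rendering places eating/drinking boxes centred on their zone (so a single
animal satisfies the occupancy rule) and lying/standing boxes uniformly on
the open floor, then applies the detector noise above. Ground truth keeps
the four-class ethogram and both budget conventions (true per-pig state
hours and rendered frame counts).

**What the simulator does and does not emulate.** It reproduces the
statistical structure the pipeline depends on: diurnal climate with
anti-phase humidity, budget fractions, rare short drinking bouts, misses,
localisation jitter, confidence spread, and systematic false positives at
a fixed scene element. It does *not* render images, does not model
correlated multi-frame failure bouts (a tarpaulin flapping for minutes, a
lighting change), social behavior, or box-shape changes with posture
transitions. Passing tests therefore demonstrate that the *inference and
arithmetic* are correct under realistic noise rates — not that any
particular detector reaches these rates on real video.

## 6. Numerical choices and degenerate inputs

* Pixel convention: origin top-left, half-open ranges
  $[x_0,x_1)\times[y_0,y_1)$; denormalization rounds to nearest integer;
  boxes past the border are clipped with a warning, not rejected; label
  round-trip is exact to the 6-decimal fixed-point format.
* Confidence filtering keeps boxes **at** the threshold (boxes with
  *lower* values are removed); ground truth without confidence passes
  untouched; the filter is idempotent and monotone in the threshold.
* Zero-area zones, empty series, all-zero budgets, mismatched budget
  keys, non-stochastic transition matrices and out-of-span timestamps are
  errors, not silent zeros.
* Union areas are exact (slab sweep), not rasterized; the test suite
  holds them against an independent per-pixel rasterization on a thousand
  random frames.

## 7. Problem sizes used by the tests

Stationary-distribution recovery is checked on three chains over three
days: lying bouts last minutes, so a single simulated day carries ~3
percentage points of sampling noise — more than the ±2 pp tolerance being
verified. The heat-modulation direction is checked end-to-end for
drinking on 12-hour observation days (where the regime gap is several
standard deviations), and at expectation level (stationary fraction ×
detectability) for eating, whose end-to-end regime gap is an order of
magnitude smaller than single-run variability at any desk-scale span.
The noisy parameter-recovery run uses a 16 animal-hour budget (three pigs
for 5⅓ h at 1 frame s⁻¹), the scale on which the published
manual-vs-automatic discrepancies are quoted.

## 8. Known limitations

* Frame-count budgets under-estimate whenever detections are missed; the
  package reports what the detector saw, as a frame-wise system must. With
  the default 5% miss rate this costs ≈ 0.5 h of lying per 16 animal-hour
  budget, visible in the simulator's comparison reports.
* The eating/drinking recovery inherits every zone-delimitation error:
  a drinker rectangle drawn too large dilutes occupancy and loses bouts.
* BGHI classification near the 74 boundary flips with ±0.1 °C of globe
  temperature; comfort timelines should be read as distributions, not
  per-record verdicts.
* The two-class detector scheme cannot distinguish a pig standing *in*
  the feeder from one eating; the feeding-window gate is the only guard,
  and an inactive feeder must be declared as such to avoid phantom
  eating.
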
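# penwatch

Precision-livestock pipeline that turns per-frame object-detector bounding
boxes from pen cameras into **ethogram time budgets** for group-housed pigs
(lying, standing, eating, drinking), alongside **thermal-comfort indices**
of the housing microclimate and standard **detection-evaluation metrics**.
It is aimed at animal-science and agricultural-engineering groups that have
(or plan to train) a detector for pig postures and want the downstream
behavior analysis — zone-occupancy inference, budget quantification,
comfort classification, validation arithmetic — as tested, reusable code.
A synthetic barn simulator stands in for the cameras and the trained
detector, so the whole pipeline runs and is testable without any video
data.

## What it computes

**Behavior inference.** Detections arrive as normalized label lines
`class_id c_x c_y w h [conf]` in the two-class scheme (lying / standing;
eating and drinking are recovered from geometry). After removing boxes with
confidence below 0.70, a standing box is reclassified using the occupancy
of the feeder and drinker regions,

```
OC = area( union of (detection boxes ∩ zone) ) / area(zone),
```

with the rule that a zone "occupied in at least 50% of its rectangle" by
standing boxes yields eating (feeder, and only during a feeding window) or
drinking (drinker, any time). Frame counts convert to hours at the native
capture rate, `hours = frames / (FPS · 3600)`, and budgets are reported as
hours and percentages of the four-behavior total.

**Thermal comfort.** From dry-bulb temperature T and relative humidity RH,
the dew point is the Magnus form `DPT = b·γ/(c − γ)` with
`γ = ln(RH/100) + cT/(b + T)`, b = 238.88, c = 17.368; the black globe
humidity index is `BGHI = BGT + 0.36·DPT + 41.5` and classifies into
stress ≤ 67 < comfort ≤ 74 < alert ≤ 76 < emergency. Physiology is normal
when rectal temperature ≤ 39.3 °C and respiratory rate ≤ 60 mov·min⁻¹.

**Evaluation.** Greedy confidence-ranked matching at an IoU threshold gives
per-class TP/FP/FN, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, average
precision as the area under the interpolated precision–recall curve, mAP50
and mAP50-95 (IoU 0.50:0.05:0.95), plus MAE, RMSE and R² for duration
agreement.

**Simulator.** Diurnal sinusoidal microclimate per thermal regime (cooled
≈ 22.6 °C / 82% RH; uncooled ≈ 30.4 °C / 55% RH), first-order Markov
behavior chains at 1 s resolution whose stationary distributions equal the
regime time-budget fractions, box rendering per behavior, and detector
noise: per-detection misses, Gaussian box jitter, Beta confidences, and
spurious standing boxes at an unused feeder.

## Worked example

```r
library(penwatch)
sc  <- generate_scenario(scenario_config("cooled", duration_s = 3600), seed = 42)
rep <- run_pipeline(sc)
print(rep)
```

```
penwatch pipeline report
  ethogram budget (hours, percent):
    lying       1.9256 h  ( 67.52%)
    standing    0.5603 h  ( 19.65%)
    eating      0.3644 h  ( 12.78%)
    drinking    0.0017 h  (  0.06%)
  thermal classes:  stress=0, comfort=96, alert=0, emergency=0
  max |manual - auto| difference: lying (0.1086 h)
  detection: P=0.994 R=0.948 mAP50=0.945 mAP50-95=0.817
```

One simulated hour of a cooled pen with three pigs: the pigs spend two
thirds of the time lying (the budget covers 3 animal-hours), all 96
microclimate records classify as thermal comfort, and the default detector
noise (5% misses, 2 px jitter, occasional false positives at the unused
feeder) costs about 5 percentage points of recall and 0.11 h of lying time
relative to the simulator's ground truth. The same stages run from the
shell via `inst/scripts/run_pipeline.R` (`generate` and `run`
subcommands), and each stage is callable on its own: `filter_confidence()`,
`infer_video()`, `summarize_budget()`, `compare_budgets()`,
`evaluate_detections()`, `dew_point()`/`bghi()`/`classify_bghi()`.

Published-table arithmetic reproduces directly:

```r
summarize_budget(c(lying = 10.913, standing = 3.215,
                   eating = 1.8518, drinking = 0.0635))
#>   behavior   hours percent
#> 1    lying 10.9130   68.02
#> 2 standing  3.2150   20.04
#> 3   eating  1.8518   11.54
#> 4 drinking  0.0635    0.40
```

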
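# poultrykpi

Phase-quality KPIs and decision support for broiler production chains.

A broiler flock passes through four phases — breeding on the farm (~7
weeks), loading into transport cages, road transport, and slaughterhouse
processing — and stress accumulated in any of them shows up in welfare and
in the final meat grade. `poultrykpi` is for precision-livestock engineers
and chain managers who already collect the raw signals (barn
temperature/humidity loggers, wrist-worn accelerometers on loading crews,
truck sensors, slaughterhouse inspection sheets) and want the standard
chain-quality indicators computed reproducibly, plus an explainable
rule-based advisor on top of them.

## What it computes

**32 KPIs, split 5/3/5/19 across the phases:**

* *Breeding* — % of rearing time with farm temperature deviating
  1.5–3 °C (warning) or >3 °C (alarm) from the farmer's optimal-temperature
  profile, and % of time the heat-stress index
  `THI = 0.8 T + (RH/100)(T − 14.4) + 46.4` sits in the alert `[70, 76)`,
  danger `[76, 81]` or emergency `(81, ∞)` band.
* *Loading* — from the wristband's tri-axial stream and the acceleration
  module `a = sqrt(ax² + ay² + az²)`: the saturation rate (rail-pinned
  seconds per minute; the measurable range is −8.00 g to +7.98 g), and the
  mean and standard deviation of the per-minute accumulation (sum of the 60
  per-second maxima of `a`).
* *Transport* — % of journey time with T > 31 °C, T < 18 °C, RH > 80 %,
  RH < 60 %, and the *abrupt movements* score: the share of samples whose
  acceleration module is signalled by a smoothed z-score peak detector
  (moving mean/SD over the previous `lag` filtered samples; a point more
  than `threshold` SDs away is signalled; `influence` controls whether
  signals move the filters; defaults 25 / 5 / 0).
* *Slaughterhouse* — a validated CSV reader/writer for the 19-field
  operator inspection template (weights, injury and defect counts, lot
  counts, binary meat grade A/B).

**Decision support:** an in-package CART learner (Gini impurity, midpoint
thresholds, deterministic tie-breaks) over historical chain-KPI tables,
extraction of its root-to-leaf paths as a disjunctive-normal-form rule set,
rule-based prediction (provably identical to tree traversal), and
`recommend()`, which filters the rules of a desired grade by the KPIs that
are already fixed and returns the residual constraints on the free ones.

**Synthetic inputs:** seeded generators plant ground truth for every input
(stratified exact band fractions, Poisson saturations, Gaussian per-minute
accumulations, rule-labelled chain tables), so the whole pipeline is
testable without proprietary farm data.

## Worked example

One simulated rearing day, a loading session and a journey, planted at the
magnitudes of a real production chain, then scored:

```r
library(poultrykpi)

fc <- gen_farm_climate(farm_scenario(duration_days = 1, seed = 2019))
round(breeding_kpis(fc$temps, fc$rhs, fc$profile), 2)
#> temperature_warning   temperature_alarm     alert_situation
#>               18.30               34.48                7.88
#>    danger_situation emergency_situation
#>                5.62               68.30

ws <- gen_wristband(seed = 2019)          # 10 min at 100 Hz
round(loading_kpis(ws), 2)
#>   saturation_rate mean_accumulation  std_accumulation
#>              0.90            122.63             55.27

j <- gen_transport(seed = 2019)           # 1 h journey at 1 Hz
round(transport_kpis(j$temps, j$rhs, j$stream), 2)
#>        low_temperature       high_temperature  low_relative_humidity
#>                   0.00                   0.00                   0.00
#> high_relative_humidity       abrupt_movements
#>                  17.00                   9.43
```

Reading: the flock spent 18.3 % of the day at mildly uncomfortable
temperatures and 34.5 % at severely uncomfortable ones; heat stress was in
the emergency band 68.3 % of the time. The wristband saturated about once
a minute (0.90/min) around a mean accumulation of 122.6 g·s per minute.
The journey stayed thermally comfortable except for 17 % of the time above
80 % RH, and the driving was abrupt 9.4 % of the time.

Feeding the chain's KPIs to the advisor's rule set:

```r
rules <- planted_quality_rules()
predict_rules(rules, c(ES = 68.30, AM = 9.32, HT = 0, HH = 17, LT = 0))
#> [1] "A"          # matched via ES > 65 & AM <= 40 & HT <= 50

recommend(rules, c(ES = 68.30), "A")
#> rule 3 -> A, remaining: AM <= 40 AND HT <= 50
#> rule 5 -> A, remaining: AM > 40 AND HH <= 20
```

With the breeding phase over (emergency exposure fixed at 68.3 %), two
routes to grade A remain: keep the journey smooth and cool, or — failing
smoothness — keep its humidity low. The low-emergency rules are discarded
because their preconditions can no longer hold.

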
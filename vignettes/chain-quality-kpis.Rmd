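---
title: "Scoring a broiler production chain: KPIs, peak detection and rule-based advice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring a broiler production chain: KPIs, peak detection and rule-based advice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(poultrykpi)
```

## The problem

Broiler chickens pass through four phases on their way to market: about
seven weeks of **breeding** on the farm, a few hours of **loading** into
transport cages, a road **transport** to the slaughterhouse, and the
**slaughterhouse** processing itself.  Stress accumulated anywhere along
that chain — heat stress in the barn, rough handling at loading, abrupt
driving, injuries discovered at inspection — degrades both welfare and the
final meat grade.  `poultrykpi` turns the raw observations of each phase
(environmental sensor series, wrist-worn accelerometer logs, truck sensors,
operator inspection sheets) into 32 objectively defined key performance
indicators (5 breeding, 3 loading, 5 transport, 19 slaughterhouse), stores
them per chain, and mines historical KPI tables for explainable
decision-tree rules that tell a chain manager which levers still lead to an
"A" meat grade.

## Time-fraction KPIs and their conventions

Most environmental KPIs are *fractions of time in a value band*.  The
package computes them as sample-count fractions: sensors log at a fixed
period (30 s on the farm by default), so the share of samples in a band
equals the share of time in it.  Three conventions matter and are applied
uniformly:

* **Missing samples** are kept as `NA` and excluded from both the
  numerator and the denominator, so sensor outages neither inflate nor
  dilute a KPI.  Irregular series are first snapped to their nominal grid,
  carrying the last value across gaps of at most twice the sample period
  (`regularize_series()`); longer outages become missing.
* **Band edges.** A temperature deviation of exactly 3 °C from the optimal
  setpoint is still a *warning* (the warning band is the closed interval
  [1.5, 3] °C); only strictly larger deviations are *alarms*.  Transport
  comfort bounds (31/18 °C, 80/60 %RH) are strict: a sample sitting exactly
  on a bound is comfortable.
* **Clock alignment.** Seconds are half-open intervals `[s, s+1)` aligned
  to integer epoch seconds, and minutes are the analogous epoch-minute
  blocks, so aggregation is deterministic and order-independent.

The optimal-temperature profile is a *step function* of farmer-provided
setpoints (`comfort_profile()`): setpoints are discrete decisions, edited
mid-rearing when the flock grows faster or slower than expected, so no
interpolation is applied between segments.

## The heat-stress index

Heat stress depends jointly on temperature and humidity.  The stress bands
used by the breeding KPIs are: index 70 to just under 76 → *alert* (birds
may start to pant), 76–81 → *danger*, above 81 → *emergency*.  The interval
between the published band edges 75 and 76 is closed by making the alert
band half-open, `[70, 76)`, so the bands are disjoint and every index value
falls in at most one of them.

The index formula itself is pluggable.  The default, registered as
`"thi_default"`, is the livestock temperature–humidity index

$$\mathrm{THI} = 0.8\,T + \frac{RH}{100}(T - 14.4) + 46.4,$$

with \(T\) in °C, which lands on the 70–81 scale the bands are defined on
(for example, 25 °C at 50 %RH gives 71.7, inside the alert band).  Any
alternative — for instance a lookup-table digitisation of a published
stress chart — can be swapped in with `register_his_formula()`; a formula
must be monotone non-decreasing in both temperature and humidity, which is
spot-checked at registration, and the band KPIs only rely on that
monotonicity.

```{r}
his_value(25, 50)
```

## Loading: wristband aggregates

The wristband logs three acceleration axes at high rate within a
measurable range of −8.00 g to +7.98 g.  Its KPIs are built from the
*acceleration module* \(a = \sqrt{a_x^2 + a_y^2 + a_z^2}\):

* **Saturation rate** — forces beyond the measurable range are invisible
  except as samples pinned at a rail, so a second is *saturated* iff any
  raw sample in it touches a rail on any axis, and the KPI is the mean
  number of saturated seconds per complete minute (0.98 reads as "the
  sensor saturates almost once a minute").  The rail comparison accepts an
  optional epsilon for hardware that clips a hair inside its nominal
  range; the default is exact equality.
* **Mean / standard deviation of accumulation** — per minute, the sum of
  the 60 per-second maxima of the module (g·s per minute); the KPIs are
  the mean and standard deviation of that per-minute series.  The standard
  deviation uses the sample (n−1) denominator by default, configurable to
  population.

Partial leading and trailing minutes are excluded from minute-level
statistics — an incomplete minute would otherwise bias the accumulation
downward.  Seconds with no samples inside a complete minute contribute 0
and are reported.

## Transport: thermal comfort and the smoothed z-score detector

Four transport KPIs are band fractions (temperature above 31 °C / below
18 °C, humidity above 80 % / below 60 %).  The fifth, **abrupt
movements**, scores the driver's abruptness: the acceleration module of
the truck stream is fed to a smoothed z-score peak detector, and the KPI
is the share of evaluated samples signalled as unstable.

The detector keeps a moving mean and a moving *population* standard
deviation of the previous `lag` **filtered** values.  A new point further
than `threshold` moving standard deviations from the moving mean is
signalled (+1 above, −1 below); a signalled point enters the filtered
series with weight `influence` only.  Conventions:

* the first `lag` samples seed the filters with the raw values and receive
  signal 0; they are also excluded from the abrupt-movements denominator,
  since no signal is defined there;
* a point at *exactly* `threshold` standard deviations is not signalled
  (signals require exceeding the threshold);
* with `influence = 0` the filters are provably unaffected by signalled
  points, so a long braking episode cannot mask subsequent ones — the
  defaults are `lag = 25`, `threshold = 5`, `influence = 0`.

```{r}
x <- c(rep(1, 40), 5, rep(1, 19))
r <- zpeak(x, zpeak_params(25, 5, 0))
which(r$signals != 0)
```

## Slaughterhouse records

The 19 slaughterhouse KPIs are recorded by operators on a fixed template,
one row per flock, read and written as CSV (`parse_slaughter_csv()`,
`write_slaughter_csv()`).  Counts are validated against their scope: the
injury/processing-defect counts against the inspected sample size (200
birds by default), `dead_in_transport` and `confiscated` against the lot
size.  `meat_quality` is the binary final grade, `"A"` or `"B"`.  The
template stores `weight_range` as a single scalar in kg, mirroring its
source; despite the name it is not an interval.

## The advisor: trees, DNF rules, recommendations

Historical chains form a KPI table (one row per chain).  `fit_cart()` is a
greedy binary recursive partitioner implemented in the package — the rule
layer needs access to every node — with these choices:

* Gini impurity for categorical targets, variance reduction for numeric
  ones (only classification trees are converted to rules);
* candidate thresholds are midpoints between consecutive distinct sorted
  feature values; the left branch is always `<= threshold`;
* deterministic tie-breaks: among equal-impurity splits the
  lexicographically smallest feature, then the smallest threshold; mixed
  leaves predict the majority class, ties to the lexicographically first
  label;
* growth stops on `max_depth`, `min_leaf`, purity, or an impurity decrease
  below `min_impurity_decrease`, which plays the role of a complexity
  parameter — no cross-validated pruning is attempted.

Every root-to-leaf path is a conjunction of threshold conditions;
`extract_rules()` returns them as a disjunctive-normal-form rule set that
partitions the feature space, so rule-based prediction
(`predict_rules()`) provably equals tree traversal, and exactly one rule
matches any complete KPI vector.  `recommend()` filters the rules of a
desired class by the KPIs that are already fixed (phases that have
happened) and returns the residual constraints on the free features — the
actionable levers.  `prune_redundant()` collapses subtrees whose leaves
all agree, which shortens the rule set without changing a single
prediction.

The bundled `planted_quality_rules()` encodes the demonstration rule
set over five cross-phase features — breeding emergency exposure (`ES`),
transport abruptness (`AM`), high humidity (`HH`), high temperature
(`HT`), low temperature (`LT`) — with thresholds 65/40/20/50/35:

```{r}
rules <- planted_quality_rules()
print(rules)
pred <- predict_rules(rules, c(ES = 68.30, AM = 9.32, HT = 0, HH = 17, LT = 0))
pred
str(recommend(rules, c(ES = 68.30), "A"), max.level = 2)
```

With only the breeding outcome fixed at `ES = 68.30`, the two low-`ES`
rules are incompatible and are discarded; the two surviving "A" rules say:
either keep the journey smooth and cool (`AM <= 40` and `HT <= 50`) or,
failing smoothness, at least keep humidity low (`HH <= 20`).

## The synthetic generators

No chain data is shipped; seeded generators produce every input with
*planted ground truth*, which is what makes the KPI engines testable:

* `gen_farm_climate()` allocates each sample to a temperature-deviation
  band and a heat-stress band by **stratified construction** — exact
  counts, values jittered strictly inside the band — so band KPIs must
  reproduce the planted fractions up to count rounding; an `iid` mode
  draws bands independently for statistical tests.  Humidity is obtained
  by inverting the default THI at a target strictly inside the planted
  stress band, which is feasible for every band combination when the
  optimal-temperature setpoints lie in [28, 29] °C (the generator enforces
  this); hot deviations are used for danger/emergency samples and cool
  ones otherwise.
* `gen_transport()` plants the humidity band fraction exactly and inserts
  spike episodes (amplitude far above `threshold` moving standard
  deviations) covering the planted share of post-warm-up samples; the
  abrupt-movements KPI is recovered *algorithmically*, so it is
  approximate (±0.5 pp in tests) rather than constructed.
* `gen_wristband()` draws each minute's accumulation from the planted
  normal distribution, splits it into per-second maxima that sum exactly
  to the draw, and inserts rail-pinned samples as a per-minute Poisson
  process; recovered KPIs match the planted ones within Monte-Carlo error
  over minutes.
* `gen_chain_dataset()` labels uniform-by-side feature draws with the
  planted rules, then flips labels with the scenario's noise probability.
  The default feature marginals put mass on both sides of every planted
  threshold with exceedance probabilities (ES 0.4, AM 0.5, HH 0.9, HT 0.1,
  LT 0.05) chosen so that the *greedy* learner's locally best first split
  is the planted root: a pure "router" feature like `ES` earns little
  immediate impurity reduction, so balanced marginals would make a greedy
  learner pick a different root even though the planted tree is the true
  model.

The planted defaults are the package's study conditions: a 49-day rearing
at 30 s sampling with warning/alarm/alert/danger/emergency fractions
18.31/34.48/7.89/5.62/68.30 %, transport with 17 % high humidity and
9.32 % abruptness, wristband aggregates 0.98/121.67/48.99.  Tests and the
acceptance script run them at desk scale — one rearing day at 30 s, 1 h
journeys at 1 Hz, 10-minute wristband streams at 100 Hz, 2000-chain
tables — sizes chosen to keep a full run in seconds while leaving enough
samples that stratified fractions are exact to well under 0.1 pp.

What the generators deliberately do **not** emulate: real barn
thermodynamics (temperature and humidity are placed by band, not by
physics), diurnal cycles, sensor drift or miscalibration, correlated
multi-sensor noise, and the biomechanics of actual catching.  Passing
tests therefore demonstrate that the *computations* are correct under the
stated conventions, not that real farms satisfy the planted distributions.

## Numerical and degenerate-input behaviour

* Empty series, or series that are all-missing after gap handling, raise an
  empty-input error: a KPI over no data is undefined, not 0.
* Streams shorter than one complete minute (loading) or than `lag + 1`
  samples (transport) raise insufficient-data errors.
* A comfort profile that does not cover the series span, an unknown HIS
  formula id, invalid detector parameters, or infeasible planted fractions
  raise configuration errors; all conditions are classed
  (`poultrykpi_*`) so callers can branch on them.
* Single-class training data yields a single-leaf tree, not an error; an
  empty feature set is a configuration error.
* Greedy splitting can park a recovered threshold a fraction away from a
  planted one when a handful of points sit between them (the midpoint rule
  is locally optimal, not gap-seeking); recovery tests therefore compare
  partitions away from a ±2 pp band around the planted thresholds and
  bound the sliver mass instead of demanding bitwise label equality.

## Known limitations

* "% of time" is a sample-count fraction; with heavily irregular logging
  the duration-weighted fraction could differ.  The regularisation step
  bounds the error by construction but does not integrate durations.
* The default heat-stress formula is a standard livestock THI on the right
  scale, but it is a package default, not a calibration to any particular
  published chart; users with a validated chart should register it.
* Whether saturation should count saturated *seconds* or raw *samples* per
  minute is ambiguous in the field; the per-second reading is used because
  the data is aggregated to seconds first, and 0.98 then reads naturally
  as "almost once per minute".
* The advisor learns association, not causation: a recommended lever is a
  branch of a fitted tree, and its real-world effectiveness depends on the
  historical table being representative.
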
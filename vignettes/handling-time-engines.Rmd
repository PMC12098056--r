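---
title: "Handling-time engines and the simplified colony model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Handling-time engines and the simplified colony model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bombusforage)
```

This vignette is the package's own account of its model: what is computed,
which parts are faithful mechanism, which parts are declared surrogates,
and what the packaged tests do and do not demonstrate.

## The question the package addresses

Mechanistic pollinator models often derive the time a bee spends gathering
one nectar load — the handling time — from floral and bee morphology:
corolla depth, glossa length, bee weight, per-flower nectar volume. That
mechanism is attractive but fragile: corolla depth is missing from the
major floral-resource databases, varies strongly within species, and the
handling-time regression has a pole where corolla depth approaches glossa
length, so small parameter errors produce enormous duration errors. The
alternative is a constant handling time, set directly from observed trip
durations. `bombusforage` implements both engines inside one simplified
colony/population model so their downstream consequences — trip durations,
foraging mortality exposure, colony energetics, year-end queen counts —
can be compared scenario by scenario.

## Trip durations

A trip to a patch at one-way distance $\Delta s$ lasts
$F = 2\Delta s/v + T_h$ with flight speed $v$ (default 5 m s$^{-1}$,
config-exposed).

### The mechanistic engine

Per-flower access time is linear in corolla depth $C$:
$T_a = 0.3 + 0.04\,C$ (seconds, $C$ in mm). Per-flower ingestion time is

$$T_i = \frac{\log_{10}(V+1)}{\log_{10}\!\big(0.3\,W^{1/3} G^{1.41} (1-C/G)^{0.4}\big)} - 0.3\,T_a + 1$$

with per-flower nectar volume $V$ (µl), bee weight $W$ (g) and glossa
length $G$ (mm). The published rendering of this regression is
typographically ambiguous; the parse above was adopted because it is
finite at $C = 0$ and has a vertical asymptote as $C$ approaches $G$ from
below, matching the regression's documented behaviour. Note where the pole
actually sits: the denominator vanishes where the logarithm's argument
crosses 1, which for $W = 0.195$ g and $G = 11.1$ mm is $C \approx
10.92$ mm — slightly *below* the glossa length. Between the pole and
$C = G$ the parse yields negative values; the implementation treats
everything at or past the pole (including $C \ge G$, where nectar is
physically unreachable) as an unbounded sentinel (`Inf`) that the cap
turns into $T_\mathrm{max}$. `plot_handling_curve()` draws the curve.

A load needs $N_\mathrm{flowers} = \lceil \mathrm{crop}/V \rceil$ flowers
(crop capacity default 120 µl), and the patch filling level
$\gamma \in [0,1]$ — current nectar stock over daily capacity, the
volume-based proxy for the fraction of flowers still filled — inflates the
search-and-access part:

$$T_h = \left(\frac{T_t + T_a}{\gamma} + T_i\right) N_\mathrm{flowers},
\qquad T_h \le T_\mathrm{max} = 3600\ \mathrm{s}.$$

Both $T_t$ (inter-flower travel, a species constant) and $T_a$ scale with
$1/\gamma$; $\gamma = 0$ returns the cap. The cap exists to keep
almost-empty patches from generating unbounded handling times.

### The fixed engine

$T_h = \mathrm{FixedHandlingTime\_s}/\gamma$, capped at $T_\mathrm{max}$,
selected by the boolean config key `FixedHandlingTime?`. It ignores $C$,
$V$, $W$ and $G$ entirely — species tables may carry dummy values for
those columns and a test verifies they are inconsequential. Setting the
constant to 3600 s makes the trip handling exactly $T_\mathrm{max}$
regardless of depletion.

## Foraging mortality

Mortality during foraging is a constant per-second hazard: high
($10^{-5}$ s$^{-1}$, the default, adapted from honeybee work),
intermediate ($2.14\times10^{-6}$ s$^{-1}$) and low
($2.75\times10^{-7}$ s$^{-1}$), both field estimates for bumblebees.
Per-trip survival is $e^{-r F}$, applied once per completed trip; the
exponential was chosen over $(1-r)^F$ because it is exactly
duration-additive, and at these rates the two differ by well under 0.1 %.
A forager that dies is removed and its load is not delivered.

## The simplified colony model

The surrounding life cycle is a declared surrogate for a much more
detailed individual-based description that is out of this package's
scope. Every constant below is exposed in `sim_params()`.

* **Calendar.** 365-day years, no leap days. Queens emerge uniformly in
  March 1 – April 15, search for nest sites until June 30 (daily founding
  probability 0.2 scaled by site availability; daily search mortality
  0.03), colonies switch to producing sexuals on July 15, and all colony
  activity ends October 31. Hibernating queens survive winter with
  probability 0.3.
* **Nest sites.** One site per hedgerow or scrub patch; the cap keeps
  colony numbers farm-like (≈ 7–14) and is the main brake on population
  size.
* **Foraging.** Each forager (30 % of workers; a founding queen forages
  alone with half the 28 800 s daily budget, the rest treated as
  incubation) takes sequential trips while the colony's nectar or pollen
  store is below target, choosing the type with the larger relative
  deficit. Patch choice maximises expected intake rate
  (expected load / expected trip duration at current $\gamma$) over
  memorised patches; with probability $\varepsilon = 0.1$ — always, when
  the memory is empty, otherwise the colony would idle — one random
  unmemorised patch joins the candidate set. Ties break to the lowest
  patch id. A trip delivers up to one crop load (120 µl nectar or 0.015 g
  pollen) and costs the store 0.07 µl of nectar-equivalent per trip
  second — a literature-scale foraging metabolic rate (~90 mg sugar per
  foraging hour). This cost term is the model's central economic lever:
  the break-even trip duration is $120/0.07 \approx 1714$ s, so any
  scenario whose trips always exceed that (fixed handling ≥ 1800 s plus
  flight) is structurally energy-negative and goes extinct — the
  mechanism, not a hard-coded outcome.
* **Demography.** Eggs (≤ 4/day, 3 during founding) develop into workers
  in 28 days; workers live 30 days. Daily consumption: 12 µl per worker,
  20 per queen, 8 µl nectar + 0.8 mg pollen per brood item. On a
  zero-nectar day half the brood starves; two consecutive zero days kill
  the colony. From July 15 surplus nectar above a five-day reserve is
  converted into hibernating queens (1200 µl + 0.05 g pollen each, at
  most one per day per colony, bounded by the worker count).
* **Pollen.** The pollen-trip mechanism is deliberately untouched by the
  engines: a stand-in base handling of 300 s divided by the pollen
  filling level, capped at $T_\mathrm{max}$.

## The synthetic landscape

`generate_landscape()` emulates a resource-poor mixed farm on 4 × 4 km: 60
point patches (habitat drawn from area fractions: semi-improved pasture
0.32, permanent pasture 0.27, maize 0.20, hedgerow 0.08, scrub 0.08,
flower-rich plot 0.05), per-habitat species with staggered flowering
windows covering early spring (queens must find food at emergence), and
daily per-patch nectar capacities of 9 000–50 000 µl (a "patch" is an
aggregated habitat element, not a plant). Stocks reset to capacity every
day inside the flowering window and to zero outside it — the time step is
one day and no sub-daily secretion model is claimed. Maize contributes
only a brief pollen pulse. Patch capacities were calibrated once so that
(i) daily offtake is a modest fraction of stock, keeping the
trip-weighted mean filling level high — which is what makes the weighted
mean trip duration essentially linear in the fixed handling time, with
slope only slightly above 1 — and (ii) mechanistic-engine runs under high
mortality persist with a few colonies and hundreds (not thousands) of
year-end queens, the qualitative signature of a resource-poor landscape.
A `richness` multiplier scales all capacities linearly for richer/poorer
variants.

What the generator does **not** emulate: real spatial autocorrelation of
habitats, within-season capacity trends, nectar concentration/viscosity,
multi-species bee communities (the tables support them; the packaged
experiments use one species). Passing behavioural tests on this landscape
therefore demonstrates internal consistency of the mechanisms, not
calibration to any real farm.

## Randomness and determinism

Each run uses one RNG stream seeded by a replicate seed derived from a
stable string hash of (master seed, scenario name, replicate index); the
seed is recorded in experiment output for audit. The same seed reproduces
a run bit-for-bit; landscape generation is seeded separately in its spec
and restores the caller's RNG state. A single per-run stream was chosen
over per-process named streams for simplicity with R's global RNG; the
cost is that adding a new stochastic process to the model shifts draws
within a run (runs remain independent, which is what the experiment
design needs).

Agent order is re-randomised daily to avoid id-order artefacts; daily
metrics are recorded after all agents act. The per-trip log is optional
(`record_trips = TRUE`) because full logs are large; the daily counters
are sufficient for every packaged summary statistic, and an instrumented
test verifies that the trip-count-weighted mean of daily means equals the
per-trip grand mean to machine precision.

## Numerical and degenerate-input conventions

Filling level of a zero-capacity patch is 0. Depletion clamps to stock;
stocks never go negative. Flowering windows are inclusive on both ends.
Handling times at $\gamma = 0$, at/past the regression pole, or with
unreachable nectar are $T_\mathrm{max}$. Trip-duration ties in patch
selection break to the lowest patch id. The queen-production floor rule
(`floor(surplus/cost)`) makes production insensitive to sub-queen
surplus.

## Problem sizes used by the packaged checks

The behavioural test suite runs the full 19-scenario grid at 5 replicates
(5-year runs, 100 initial queens) on the default landscape — the
package's chosen desk-scale design point, small enough to run routinely
on a laptop core; the published design's 20 replicates are available by
setting `replicates = 20` in `run_experiment()`. Unit tests use smaller
landscapes and 1–2-year runs.

## Known limitations

* The colony model is a surrogate: no nursing stimuli, larval cohorts,
  male production, badger predation, or weight growth; glossa length is
  drawn per colony, not per forager.
* The mechanistic engine's parse of the ingestion regression is an
  adopted resolution of an ambiguous rendering; no alternative parse is
  implemented.
* Population sizes on the synthetic landscape are calibration targets
  only in order of magnitude; absolute queen counts are not comparable to
  any field system.
* Mortality differences at long handling times are partially masked by
  density dependence (lower mortality → more workers → deeper depletion →
  lower net intake), so low- and intermediate-mortality populations can
  be statistically indistinguishable there.
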
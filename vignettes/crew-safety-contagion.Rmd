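---
title: "Modelling the social contagion of safety violations in construction crews"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the social contagion of safety violations in construction crews}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`crewsim` couples an agent-based simulation of construction workers and
their supervisors on a cell-based virtual site with a daily
system-dynamics (SD) layer that aggregates agent events into
organizational pressures and feeds management parameters back to the
agents. The object of study is the *social contagion of safety
violations*: the process by which workers assimilate their crew's hazard
tolerance and become more (or less) willing to work around safety
procedures.

### The virtual site

The site is a 92 x 84 grid of 1 m^2 cells. 3600 cells, arranged as four
30 x 30 building blocks separated by two road corridors, are under
construction; each building cell carries

* an integer *workload* drawn uniformly from 1..20 (units of work to
  complete the cell's task),
* a static *hazard level* drawn from `Triangular(0, mode, 200)` with
  mode 50, 100 or 150 (low / modest / high hazard sites),
* a *situational constraint* flag (e.g. missing protective equipment),
  drawn with probability `kappa * workload / 20` so that more complex
  tasks are more constraint-prone.

Three tower cranes pivot at block centroids; the cells under a jib (20
cells long, rotating 15 degrees per tick) form dynamic danger zones with
hazards drawn uniformly from [160, 200]. The effective hazard of a cell
is the maximum of its static and crane hazard. When a cell's workload is
fully consumed the cell is immediately redrawn (workload, hazard,
constraint flag): the site is a continuing project at steady state,
which is what per-day and per-year incidence metrics presuppose.

### Workers

100 workers in 5 crews of 20 alternate between *approaching* (moving to
a neighbouring cell with workload) and *implementing* a task. At task
start the worker checks the environment:

1. *situational checking* — an unremoved situational constraint forces a
   **situational violation**;
2. *safety checking* (risk homeostasis) — if the effective hazard `h` is
   below the worker's acceptable hazard `AR_i`, the worker commits a
   **routine violation** (unless warned by a manager); otherwise the
   task is performed **normally**.

Violating tasks run 20% faster (`productionIncr = 0.2`, the
safety-productivity tradeoff) and, at completion, end in an accident
with probability `alpha * h / 200`, in a near-miss with probability
`r * alpha * h / 200`, and otherwise without incident. A near-miss
lowers `AR_i` by 5, an accident by 50 and stops the worker for 3 days.
Initial `AR_i ~ U(20, 180)` excludes absolute risk aversion/seeking.

### Social contagion

Once per day each worker updates a perceived crew tolerance `TC_i` from
the behaviour of the 19 crew mates over a trailing 28-day memory window,

`TC_i(t) = (1 - 1/m) TC_i(t-1) + (1/m) mean_c HA_c(t)`,

blends it with the management tolerance `TM` by the attitudinal
ambivalence weight `w`,

`TR_i(t) = w TC_i(t) + (1 - w) TM(t)`,

and adapts the acceptable hazard at the worker's contagion probability
`cp_i ~ U(0.1, 0.9)`:

`AR_i(t) = (1 - cp_i) AR_i(t-1) + cp_i TR_i(t)`.

All three updates are convex combinations, so tolerances stay inside
the range of their inputs; `AR_i` is additionally clamped to [0, 200].

**The coworker index `HA_c`.** Two readings are implemented. The
default, `contagion_index = "exposure"`, averages the effective hazard a
coworker was exposed to over *all* tasks completed in the window —
"the average hazard level the coworker is exposed to during task
implementation". The alternative, `"violation_load"`, sums hazards only
over the coworker's *violations* (still divided by total tasks), i.e. a
per-task violation-hazard load. The distinction matters structurally:
under the violation-load reading the crew index is an order of magnitude
below the management tolerance (a few hazard units against `TM = 50`),
so the blend `TR` can never exceed `TM` and the crew can never be more
permissive than management. That contradicts the contagion narrative the
model exists to express (and the baseline statistics it is validated
against, which require mean acceptable hazards slightly *above* the
management anchor). The exposure reading makes the crew norm track the
ambient hazard (~100 at a modest-hazard site), so ambivalent workers
drift upward and the documented positive associations between coworker
violations, ambivalence, production pressure and acceptable hazard all
emerge with realistic magnitude. We therefore default to the exposure
reading and keep the violation-load variant available for comparison.

### Management

One supervisor per crew patrols by relocating, each tick, to a randomly
chosen active crew member. When a worker starts a task within the
inspection distance (Chebyshev metric, grid-native) and the cell hazard
exceeds the management tolerance `TM`, the manager removes a present
situational constraint with probability `improvement_rate` (safety
improvement) or averts a pending routine violation with probability
`feedback_rate` (safety feedback; the warned task is performed
compliantly and is not counted as a violation). Feedback deliberately
does not alter `AR_i`: the persuasive influence of management is carried
by `TM` through the contagion blend, keeping the two channels distinct.

### System dynamics

Each day, from trailing 7-day tallies:

* per crew, perceived safety-specific social support
  `SS = min(1, (improvements + feedback) / violations * 100)` (1 when
  there are no violations to support against), perceived production
  pressure `PP` (the crew's relative productivity shortfall times 100,
  capped at 1, zero at or above average), and ambivalence
  `w = min(1, max(0, 0.68 PP - 0.13 SS))`;
* the intervention and violation counts behind `SS` come from the
  trailing 7 days (matching the weekly framing of the incident stocks),
  while the productivity comparison behind `PP` uses the previous day's
  crew outputs (`pp_window_days = 1`). The window length matters more
  than it looks: crews of homogeneous workers differ in *weekly* output
  by well under 1%, so a 7-day average pushes the scaled shortfall
  below the `* 100` auxiliary's saturation threshold, collapses
  ambivalence toward zero and pins every acceptable hazard to the
  management tolerance — day-to-day comparisons keep the pressure
  auxiliary operating and the crew-norm channel alive;
* globally, the safety performance gap
  `(nearmisses + 10 accidents - safeGoal) / safeGoal` clamped to [0, 1]
  as the safety control pressure `SCP`; and the management outputs
  `feedback_rate = improvement_rate = max(1 - proacMan, SCP)`,
  `distance = 10 * max(1 - proacMan, SCP)`,
  `TM = min(100 proacMan, 100 (1 - SCP))`.

At the baseline (`proacMan = 0.5`, no incidents yet) these yield rates
0.5, distance 5 and tolerance 50. The distance coefficient is 10, not
5, precisely so that the documented baseline distance of 5 cells holds
at `proacMan = 0.5`. An accident keeps `SCP = 1` for the following
week — a reactive "crackdown" with full inspection rates, reach 10 and
zero tolerance — after which the system relaxes.

The `* 100` scaling parameters make `SS` effectively binary in
practice; `PP`, however, operates in its graded regime because crews of
homogeneous workers differ in weekly productivity by well under 1%.
Both scalings are configurable; a scaling of 1 produces fully graded
auxiliaries.

## Time structure and the productivity identity

Days are divided into 10 ticks (0.1 day). Tasks consume time
continuously: each tick an implementing worker spends its full tick
budget on the current task; when a task completes mid-tick the leftover
budget carries into the next task, and movement to a neighbouring cell
at a task boundary is instantaneous. Consequently a fully compliant
worker produces exactly `production_speed = 20` units per day — a
useful conservation identity that the test suite checks exactly — and
all productivity shortfalls/gains in the metrics are attributable to
modelled causes (accident stoppages, violation speed bonuses), not to
discretization. The cost of this choice is that baseline productivity
sits slightly *above* 20 (violations add speed), whereas an external
benchmark of ~19.35 units/worker/day implies a few percent of
walking/idle time that the model deliberately does not include; the
discrepancy is confined to that one indicator and is documented where
the indicator is reported.

Contagion (daily) runs before the day's ticks, so experiential
decrements (-5/-50) act on the already-adapted value; the SD update uses
only completed days, so day 1 reproduces the documented initial
management outputs exactly. `TC_i(0)` is initialized at the crew mean
of initial acceptable hazards — a neutral start with no contagion shock.

## Calibration

The outcome law's constants are not externally observable and are
calibrated, as part of the model definition, against four baseline
benchmarks at the modest-hazard site: about one violation per three
worker-days, a ~0.11 situational share, ~3.2 accidents per 100
full-time worker-years, and a near-miss:accident ratio near 8:1
(Heinrich-like). Because near-miss and accident probabilities share the
same hazard dependence, the pooled near-miss:accident ratio equals `r`
by construction; `alpha` scales the accident rate; `kappa` scales the
situational share. The shipped defaults are `alpha = 0.00165`,
`r = 8.18`, `kappa = 0.0345`; at these values 30 verification
replicates of the baseline give a violation ratio of 0.320, a
situational share of 0.105, 3.0 accidents and 24.9 near-misses per
100 worker-years, and a pooled near-miss:accident ratio of 8.2.

## Experiments

* `run_baseline_validation()` aggregates replicate metrics and fits
  pooled per-worker regressions of mean acceptable hazard on coworker
  violations, crew ambivalence and crew production pressure (sign
  checks of the contagion signature).
* `run_sensitivity()` raises `safeGoal`, `proacMan`, the median
  contagion probability and `productionIncr` by 50% one at a time,
  with common random numbers against the base runs.
* `run_fed()` executes the replicated 2^4 factorial over
  safeGoal {0.5, 2}, proacMan {0.2, 0.8}, median contagionPro
  {0.2, 0.8} and productionIncr {0.08, 0.32};
  `standardized_effects()` estimates all 15 effects by orthogonal
  contrasts with replicate-pooled error and ranks them in Pareto order.
  The significance line is the computed t-critical value at alpha =
  0.05 with `16 (n - 1)` degrees of freedom, not a fixed constant.
  Under factorial manipulation of the median contagion probability `M`,
  per-worker draws are `clamp(u_i + (M - 0.5), 0.01, 0.99)` with
  `u_i ~ U(0.1, 0.9)`: the baseline spread is preserved while the
  median shifts.

## What the generator emulates — and what it does not

The simulator self-generates all inputs; there is no external data. It
emulates a steady-state project with homogeneous worker skill, crew-only
social networks (no cross-crew contagion), perfect hazard recognition,
and management attention limited by distance and probability. It does
not model material logistics, congestion, proximity-weighted influence,
training or technology-based monitoring. Passing tests therefore
demonstrate internal consistency and reproduction of aggregate
empirical benchmarks, not predictive validity for any particular real
site.

A structural limitation worth stating plainly: because the contagion
step is a convex combination, the *equilibrium* acceptable hazard is
set by the ambivalence blend of crew norm and management tolerance,
and the contagion probability `cp` controls only how fast workers
track it. Raising the median `cp` therefore raises violations through
variance tracking (workers follow tolerance swings such as
post-accident crackdowns more closely, and violation counts are convex
in the acceptable hazard) and lowers them through the initial
transient (high-tolerance starters converge down faster). The net
effect is positive but modest at the baseline, and can invert at
factorial corners where the management anchor is far below the initial
tolerance range. External accounts that attribute a large positive
main effect to the contagion probability are not reproducible from
these update equations alone; the factorial analyses here report
whatever sign and magnitude the equations produce.

## Numerical choices and problem sizes

Tick length 0.1 day resolves sub-day tasks (mean task ~0.5 day);
budget comparisons use an absolute guard of 1e-12 days. Replicate
studies in the package documentation use 50 runs of the full 100-worker
x 250-day baseline; the test suite exercises the same code paths at
reduced replicate counts and horizons (documented in each test), which
widens Monte-Carlo bands but leaves all structural identities exact.
Degenerate inputs are handled explicitly: zero violations give full
social support, a zero crew-average productivity gives zero pressure,
zero accidents make the near-miss:accident ratio undefined (reported as
missing), and a worker with no completed tasks contributes a zero
coworker index.

## Example

```{r, eval = FALSE}
library(crewsim)
r <- run_simulation(simulation_config(), seed = 1)
compute_metrics(r)

# factorial screening at the modest hazard level
fed <- run_fed(hazard_mode = 100, n_runs = 10, seed = 1)
standardized_effects(fed$raw$ratio_routine, fed$raw$point)
```
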
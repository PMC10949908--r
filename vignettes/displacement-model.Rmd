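---
title: "Modelling conflict-induced displacement with hierarchical agents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling conflict-induced displacement with hierarchical agents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(displaceabm)
```

## The problem and the model

Forced migration — people fleeing a shock such as armed conflict — is
poorly served by classical migration models (gravity, radiation), which
have no channel through which discrete violent events can drive flows.
`displaceabm` models the *initial displacement* wave directly: a synthetic
population of person agents, partitioned into georeferenced households,
reacts daily to a stream of conflict events, and the aggregate of their
micro-decisions is the daily outflow, which can be disaggregated by age,
gender, and administrative region.

Agent decisions follow the Theory of Planned Behavior, whose three
constructs map onto the model stages as follows.

**Attitude.** The observed impact of event $j$ (intensity $I_j$, day
$T_j$, location $L_j$) on an agent at location $x_i$ on day $t$ is

$$f'(i,j,t) = \frac{I_j}{\Delta T(t,T_j)^{\tau}\,\Delta S(x_i,L_j)^{\delta}},
\qquad \tau > 1,\ \delta > 1,$$

with $\Delta T = t - T_j$ in days and $\Delta S$ the haversine distance in
km. Attitude is the sum over all *past* events ($T_j < t$, strictly):
$f(i,t) = \sum_{T_j < t} f'(i,j,t)$. The power-law denominator in elapsed
time acts as an implicit discounting of older events.

**Perceived behaviour control.** Impact is perceived through a
group-level risk-proneness multiplier $\beta_i$ and a memory-retention
term:

$$\tilde f(i,t) = \beta_i f(i,t) + \theta \tilde f(i,t-1),
\qquad 0 \le \theta \le 1,$$

and converted to a daily migration intent by a logistic function

$$p'(i,t) = \frac{1}{1 + Q e^{-v\tilde f(i,t)}},$$

where $Q$ sets the no-risk migration probability $p'(0) = 1/(1+Q)$ and
$v$ the growth rate of intent in perceived risk.

**Subjective norm.** Intent aggregates to households as the arithmetic
mean over members, an initial household decision is drawn
$m'(k,t) \sim \mathrm{Bernoulli}(p(k,t))$, and a synchronous
peer-threshold pass over the household network finalises it: a household
is forced to migrate when more than $I_{hi}$ of its neighbours intend to,
forced to stay when fewer than $I_{lo}$ do, and otherwise keeps its own
decision. Migrating households are classified refugee or IDP, then
removed: their members skip the perception–action loop for the rest of
the run and contribute zero to neighbour sums.

Destination choice, return migration, and onward moves of the displaced
are outside the model's scope; it is a model of first displacement during
the shock period, when data are scarcest.

## Parameters

| name | meaning | domain | default |
|---|---|---|---|
| `tau` | temporal decay exponent | $>1$ | 1.5 |
| `delta` | spatial decay exponent | $>1$ | 2.0 |
| `theta` | memory retention per day | $[0,1]$ | 0.8 |
| `v` | intent growth rate | $>0$ | 0.5 |
| `Q` | no-risk migration control | $>0$ | $10^4$ |
| `I_hi`, `I_lo` | peer thresholds (neighbour counts) | integers, $I_{lo} \le I_{hi}$ | 8, 1 |
| `b`, `w` | bias / conflict scales | $[0,1]$ | 1, 1 |
| `refugee_prob` | border-crossing share of migrants | $[0,1]$ | 0.6 |
| `decision_lag` | days from decision to counted crossing | $\ge 0$ | 0 |

The decay parameters and $\theta$ transfer across conflict settings;
$v$, $Q$ and the thresholds are the ones a new setting should recalibrate.
The scales $b$ and $w$ fold into the effective growth rate $v\,b\,w$;
since both lie in $[0,1]$ they do not change the range of $v$, so
calibrating $v$ alone subsumes them and they default to 1.
`Q = 10^4` makes spontaneous no-risk migration negligible
($p'(0) = 10^{-4}$ per household-day); demonstration configurations use
smaller $Q$ so that scaled-down worlds produce visible flows.

## Numerical choices

* **Floors.** $\Delta T$ is floored at 1 day (yesterday's events have
  $\Delta T = 1$) and $\Delta S$ at 1 km, preventing division blow-ups at
  an event's own location and making the kernel's trivial anchor
  ($I = 1, \Delta T = \Delta S = 1 \Rightarrow f' = 1$) exact. Both
  floors are configurable.
* **Event-horizon truncation.** Events older than 30 days, or whose
  single-event impact falls below $10^{-9}$, are dropped from the
  attitude sum. With $\tau > 1$ the discarded tail is negligible and the
  daily cost stays linear in (agents × recent events).
* **Update order within a day.** Perception → household mean → Bernoulli
  draw → one synchronous threshold pass reading initial decisions only →
  destination classification → removal. Because the threshold reads
  $m'$, not $m$, no fixed-point iteration arises.
* **Initialisation.** $\tilde f(i,0) = 0$: agents start with no
  perceived risk. (The alternative $\beta_i f$ start only shifts the
  first day; the geometric-accumulation tests cover both conventions.)
* **Randomness.** One seeded stream per simulation, consumed in a
  documented order — per day, one uniform per active household in
  ascending household id for the decision, then one per newly migrating
  household for classification. Classification draws are consumed even
  when the martial-law rule forces IDP, so toggling that flag does not
  shift the stream. Runs are bitwise reproducible from the seed.
* **Threshold semantics.** The neighbour sum counts *households* (the
  literal reading), not fractions of the neighbourhood; thresholds are
  configurable integers. Boundary sums ($I_{lo} \le \Sigma \le I_{hi}$)
  defer to the household's own decision.

## The household network

The network construction is a pluggable design point. The default rule
connects households within a radius (1 km) capped at the 20 nearest by
haversine distance, with ties broken by distance then id, and
re-symmetrizes after capping by keeping an edge if either endpoint
retained it. Bounded degree keeps the integer thresholds on a fixed
scale and the engine linear in households. At reduced population scale
the matched-density choice matters: a scaled-down world is spatially
sparser than the full-scale population it emulates, so demonstration
configurations widen the radius (5 km for the 500-household worlds used
in the tests) to restore realistic neighbourhood sizes (median degree
roughly 5–10).

## The synthetic population generator

The generator emulates the *structure* of a ~46 M-person, ~19 M-household
national population at whatever scale is requested: mean household size
about 2.4 (sizes 1–6), female share 53.8%, a three-bin age pyramid
(18% under 18, 65% 18–64, 17% elderly), and households scattered with
Gaussian dispersion around weighted regional centroids carrying
admin-1/admin-2 labels. Risk proneness is assigned at the group level
(children and elderly 1.2, adults 1.0 by default), reflecting that these
groups are more affected by violence; the package deliberately does not
add per-person noise that the behavioural motivation does not support.

What it does **not** emulate: real census micro-structure (family
composition, urban/rural gradients within regions), real administrative
geometry, correlations between age and location, or population change
over time. Passing tests on generated worlds therefore demonstrates the
correctness and calibration behaviour of the *mechanism*, not predictive
validity for any real conflict — that requires a real synthetic
population and real event data at full scale.

Event intensity uses
$I = w_{\mathrm{type}}\,(1 + s \ln(1 + \mathrm{fatalities}))$ with all
type weights 1 and $s = 1$ by default — positive, monotone in
fatalities, and graceful for zero-fatality events — and is swappable
through configuration, as is the event-type filter (battles,
explosions/remote violence, violence against civilians by default).
Counterfactual scenarios are consumed as event lists; the bundled
sampler draws per-day Poisson counts with Gaussian spatial scatter per
component from a user-specified intensity, which keeps scenario analysis
self-contained without fitting a point-process forecast model.

## Calibration

Calibration fits a subset of parameters (default $v$ and $Q$) to an
observed daily border-crossing series by coordinate descent: each free
parameter in turn is line-searched on a bounded grid (integer grids for
the thresholds), accepting the argmin only when it does not increase the
loss, so the loss trace is nonincreasing by construction; a cycle that
improves the loss by less than the tolerance stops the search.

The objective simulates a small number of replicates, averages their
daily refugee series, applies a 7-day centred moving average to both the
simulated and observed series, and returns the RMSE (default) or
$1 - \mathrm{PCC}$. RMSE is the default because it constrains the scale
of the flow, which a correlation cannot. Two variance-control choices
make the stochastic objective tractable for a grid-based optimiser:
**common random numbers** (the identical replicate seed stream is reused
for every parameter evaluation, so the objective is a deterministic
function of the parameters) and replicate averaging. $\theta$ is held
fixed by default since literature recommendations exist for memory
decay; it can be freed explicitly.

On the demonstration scale — 500 households, 30 days, two conflict
theatres emitting 15 events/day each — self-generated series are
recovered with smoothed-series PCC above 0.9, and the fitted loss is at
or below the loss at the generating parameters. The event density of
that world was chosen so the daily series carries temporal structure
above its own sampling noise (at a few events per day, a 500-household
world produces so few migrations per day that even the generating
parameters cannot correlate with a single observed realisation); this is
a property of desk-scale worlds, and full-scale runs with tens of
millions of agents do not face it.

## Reporting conventions

Demographic disaggregation uses children (<18), adults (18–64) and
elderly (65+); the at-risk band for the sexual-violence calculator is
women aged 17–50, matching how such flows are reported. The "active
military presence" proxy for that calculator is at least one retained
conflict event within 30 km during the 7 days preceding the migration
decision — the operationalisation is exposed as arguments. Report tables
round thousands to integers and percentages to the precision of the
quantity being compared.

## Known limitations

* One-shot migration: no return, onward or cascading moves, and no
  destination model.
* Static peer network over the run; a dynamic peer effect (e.g. widening
  neighbourhoods as regions deplete) is a plausible extension.
* Actor-agnostic events: the model does not distinguish who initiated an
  event, though actor identity plausibly shifts the refugee/IDP split.
* The refugee-vs-IDP classification is probabilistic (with an optional
  martial-law rule barring households whose only adults are men aged
  18–60 from crossing); a behaviourally richer rule can be plugged in
  behind the same interface.
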
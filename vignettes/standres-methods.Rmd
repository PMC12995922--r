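---
title: "Quantifying stand-level resilience with standres"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stand-level resilience with standres}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(standres)
library(dplyr)
```

## The model in one page

`standres` asks a management question: does establishing a regeneration
cohort in a canopy gap *before* rotation age make an even-aged stand more
resilient — faster to recover its capacity to provide ecosystem services
after a disturbance — and what does that resilience cost?

The system variable is the present value of future ecosystem-service
provisions,

$$V_{ES} = \mathbb{E}\Big[\sum_{t=0}^{\infty} p_{ES,t}\,(1+r)^{-t}\Big],$$

evaluated for two services: net revenues from timber (discounted at
1.5 % p.a.) and aboveground carbon sequestration (0.5 % p.a., reflecting
the lower time preference attached to non-monetary services). Because a
stand's transitions depend only on its current cohort composition, each
discrete *stand state* — (regime, leading-cohort age, gap-cohort age if
present, leading share) — has one expected $V_F$ and one $V_C$. The
resilience metric is the time $t_{recov}$ a disturbed stand needs to lift
$V_{ES}$ back above a reference threshold; the performance metric is the
soil expectation value (SEV), the value of the whole future management
sequence started on bare soil.

## Simulation stage

Time advances in 5-year steps. A stand holds one or two age-homogeneous
cohorts. The clear-cut baseline plants, thins per an age-indexed yield
table, harvests everything at rotation age $u = 85$ and replants. A
gap-cut regime additionally removes a share $s_{gap} \in \{0.10, \dots,
0.30\}$ of the canopy at stand age $age_{gap} \in \{20, 40, 60\}$,
creating a second cohort; both then grow in parallel, each harvested at
its own age 85. The 5 × 3 grid plus baseline gives 16 regimes.

Disturbance is a stochastic, age-dependent survival process. A survivor
function $S(a)$ (default: Weibull with scale 200 yr and shape 2.75, so
hazard increases with age) is converted to 5-year-step failure
probabilities $hz(a) = 1 - S(a+5)/S(a)$. At every step one uniform draw
$y$ for the whole stand is compared with each cohort's hazard; a cohort
fails completely when $y \le hz$, triggering salvage logging at degraded
prices (74 % price, 115 % cost) and immediate replanting at doubled cost.
Sharing the draw across cohorts correlates their failures: under
age-increasing hazards the sheltered cohort can only fall together with
the leading one. Non-leading cohorts are less wind-exposed (shorter for
their age), so their hazard is scaled by
$red_{hz} = \mathrm{clamp}(1 - (b_0 + b_1(1-s))\,\Delta age,\; red_{min},\; 1)$
with defaults $b_0 = 0.002$, $b_1 = 0.004$ per year and floor 0.3 — the
simplest form that strengthens with the age difference and weakens with
cohort size. Leading cohorts keep their full hazard (gap-edge wind loading
and longer-term edge stability gains are assumed to cancel).

Draw streams are pure functions of `(seed, run)` and are reused across all
regimes within a run (common random numbers), so every disturbance impulse
has a direct counterfactual analog in every regime — the foundation of the
event-level pairing below.

Growth follows the yield table: per step a cohort's gross increment is the
tabulated volume difference plus the thinning removal; removals are valued
at the table's thinning DBH, and the table's missing young ages (below 15)
are filled linearly from zero. Two competition adjustments act on
increments: gap regeneration below retained canopy grows slower
($m_{supp} = \mathrm{clamp}(1 - (c_0 + c_1(1-s))\,\Delta age,\, 0.4,\, 1)$,
$c_0 = 0.004$, $c_1 = 0.006$), and the leading cohort accelerates
temporarily after a gap cut
($m_{acc} = 1 + 0.5\,s_{gap}\max(0, 1 - t/15\,\mathrm{yr})$).
Other unequal-aged neighbours are assumed not to interact. Carbon
provision is the gross increment times 205 kg C per m³ (410 kg m⁻³ wood
density × 0.5 carbon fraction); harvests do not generate negative carbon
provisions in the default gross-increment mode.

## Value estimation stage

$V_{ES}$ is not computed in closed form; it is estimated by Monte-Carlo.
Each regime is simulated for many runs of 2000 years; a 1000-year window
rolls along every provision series, discounting its content to the window
start. At the applied rates the truncated tail is negligible (relative
error below $(1+r)^{-1000} / (1 - (1+r)^{-u}) \approx 5\times10^{-7}$ for
net revenues). Samples whose window would overshoot the series end are
dropped, and each remaining sample is filed under the stand state at the
window start. The state recorded is the *pre-event* state: the window
starting at $t$ includes the cash flow of the events at $t$, so a state's
mean is the genuine Markov expectation including the current step's
disturbance risk. This choice reproduces the characteristic even-aged
sawtooth — $V_F$ rising with stand age, peaking at harvest, resetting to
the SEV — and makes the bare-soil state's value the SEV itself; since
every run starts from bare soil, the first sample of each run *is* that
run's SEV, which is how the performance distributions are extracted.

At the defaults (1000 runs × 2000 yr per regime) even rare states collect
enough samples; the shipped analyses use scaled-down sizes (the acceptance
script runs 150 runs per regime, package examples and tests 3–100) chosen
so the estimator's structural properties are exercised at interactive
speed, and `aggregate_by_state()` flags states under a configurable
minimum sample count rather than trusting them silently.

## Assessment stage

The recovery threshold per service is the average baseline $V$ — the
unweighted mean over all sampled steps and runs of the clear-cut regime (a
time-occupancy mean; the model states no other weighting). Disturbance
events are classified by the pre-event state and failure set:

1. complete failure with no regeneration present,
2. complete failure of a two-cohort stand,
3. failure of only the older cohort,
4. failure replacing a former gap cohort that had become leading.

Estimated state values are re-joined onto each trajectory to form $V$
paths. For each (run, step) where either member of a regime/baseline pair
registers a failure, both regimes' recovery times are measured from that
step and differenced (gain = baseline − gap). Interpolation between the
two bracketing grid points locates the crossing; stand-replacing events
start from the regime's bare-soil value at the event time (a
stand-replacing disturbance resets $V$ to its bare-soil default), partial
events from the first post-event sample (their immediate post-state, which
contains an age-0 cohort, is never itself a sampled pre-event state), and
an undisturbed counterpart contributes the — possibly zero — time its own
path needs to reach the threshold from that step. Events whose crossing is
not observed before the path ends are censored: excluded from means,
reported in counts.

The trade-off metric per gap regime is
$\tau = \overline{\Delta SEV} / \overline{\Delta t_{recov}}$ — the SEV
change accepted per year of average recovery-time reduction. A regime is
*dominant* when it gains resilience at no SEV cost (positive mean gain,
non-negative SEV change).

## Design decisions worth knowing

* **Hazard timing.** Hazards are evaluated at start-of-step cohort age,
  before the step's management and growth.
* **Salvage volume.** A failed cohort is salvaged at its full
  pre-disturbance standing volume under the degraded factors; partial
  damage fractions are out of scope.
* **Re-triggered gap cuts.** A regime's gap cut fires whenever the stand
  is again a single cohort passing `age_gap` (after stand-replacing
  disturbances); a two-cohort stand never receives a second gap cut, and
  a former gap cohort can itself be gap-cut only once it is the sole
  cohort.
* **Equal-aged cohorts merge**, which keeps the state space at most two
  cohorts after a stand-replacing loss of a two-cohort stand.
* **State key.** Values are keyed on (regime, leading age, gap age,
  leading share). The share is needed because the same age pair can recur
  with swapped shares after leading-cohort replacements; cohort origin is
  deliberately excluded (a coarsening — salvage-origin and
  planting-origin cohorts of equal age are pooled).
* **Modifier bookkeeping.** Modifiers scale the tabulated increment;
  volume deficits persist additively (a released cohort converges back
  toward the table), thinning removals stay proportional to the cohort's
  effective stocking, and DBH follows a cohort's accumulated "growth age"
  (5 yr × modifier per step), so suppressed timber is also smaller, not
  just scarcer.
* **Undefined trade-off.** With a zero mean recovery gain, $\tau$ is
  reported `NA` rather than an infinity.

## What the synthetic defaults are — and are not

Three parameter groups are intentionally pluggable because their empirical
sources are external publications and packages: survivor-curve
coefficients, the regional yield table, and the DBH-dependent
price/cost functions. The shipped defaults are synthetic stand-ins with
the right structure (monotone survival with increasing hazard; sigmoidal
Chapman–Richards volume growth to ~614 m³ ha⁻¹ at age 85 with
declining thinning fractions; price rising and harvest cost falling with
DBH around a 92.47 EUR m⁻³ reference price). All structural and
closed-form tests hold for any admissible parameterization, and the
pipeline's aggregate numbers (recovery baselines near 48 yr financial /
8 yr carbon at the defaults) are of a plausible order — but absolute
levels, gain signs, and τ values move with the parameter tables. In this
synthetic world most gap-cut regimes pay a noticeable SEV penalty (early
small-DBH harvests are valued poorly by the default price curve), and a
lower SEV level feeds back into longer average recoveries relative to the
baseline threshold: mean recovery gains hover around zero — slightly
positive for the best regimes, negative for the costliest — even though
gap regimes do shift the disturbance mix towards the milder partial types
3/4. With empirically ported tables, where gap regimes break even on SEV,
the same machinery tips the balance the other way. Conclusions about real
stands require loading ported coefficients via `read_run_config()` /
`sim_params()`.

The generator also does not emulate: partial cohort damage, more than two
cohorts, climate as anything richer than two provenance scalars, timber
price stochasticity, or soil/deadwood carbon pools. Passing tests
therefore demonstrate the estimator and assessment machinery, not a
calibrated forecast for any real stand.

## A worked example

```{r example, eval = FALSE}
cfg <- run_config(seed = 1, n_runs = 60, series_years = 2000,
                  sizes = c(0.1, 0.3), ages = c(20, 60))
ex <- run_experiment(cfg)
tidy(ex)       # per-regime gains, SEVs, tau
glance(ex)     # thresholds, baseline recovery, best trade-offs
autoplot(ex)   # gain-vs-tau overview
```

Sample sizes here are the package's choice for an interactive example;
the full study conditions (`run_config()` defaults: 1000 runs × 2000 yr)
are a drop-in replacement.
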
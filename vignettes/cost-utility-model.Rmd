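---
title: "A Markov cost-utility model of unilateral cochlear implants in adults"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cost-utility model of unilateral cochlear implants in adults}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The decision problem

Adults with severe to profound sensorineural hearing loss can receive a
unilateral cochlear implant (UCI) or continue with acoustic hearing aids —
or with nothing, if aids give them no benefit. The implant improves
hearing-related quality of life for the rest of the recipient's life, but
carries surgical adverse events, device failures, recurring programming and
maintenance costs, and sound-processor replacements. Because benefits and
costs accrue over decades while mortality steadily removes the cohort, the
natural evaluation framework is a discrete-time Markov cohort model.

`cochleaCEA` evaluates two scenarios, each with its own ICER, matching how
the candidate population splits clinically:

* **traditional candidates** (no pre-implant benefit from hearing aids):
  UCI versus no hearing aid;
* **marginal candidates** (some pre-implant benefit): UCI versus a pair of
  hearing aids with an assumed 50% compliance.

Settings: health-system perspective, six-month cycles from the implant
surgery (cycle 0) at average age 52.8, lifetime horizon truncated at age
100, 3.5% annual discounting of costs and QALYs, 2018 GBP.

## Model structure

`model_states()` lists the eleven states. The implant arm starts entirely
in `UCI_well`. During the first cycle the cohort is exposed to the
short-term surgical adverse events (dysgeusia 0.065, vertigo 0.194,
tinnitus 0.036, wound infection 0.015). Treating the events as independent,
survivors enter the one-cycle tunnel state `UCI_st_ae` with the joint
probability $1-\prod_i(1-p_i) \approx 0.284$; the tunnel's utility
decrement is the *conditional* expected disutility, so at cohort level the
decrement equals the probability-weighted average
$\sum_i p_i d_i = 0.010132$ exactly — the standard expected-disutility
rule. Long-term vertigo (probability 0.014) is a separate lifetime state
with a 0.033 decrement and one GP visit per year.

Device events are hazards on every later cycle:

* **internal failure** — the cohort splits at the decision node: with the
  discontinuation probability 0.077 the recipient stops using implants
  (explant or keep the faulty device in place, an even split by default,
  exposed as `p_explant_given_discontinue`), otherwise they are
  re-implanted, paying the re-implant cost and facing the surgical
  adverse-event risks again;
* **external failure** — replace the processor (£5,270) or cease, with the
  same discontinuation probability deciding;
* **processor upgrade** — a cost-only renewal process (below).

Recipients who cease after explant revert to their pre-implant support:
marginal candidates to hearing aids (compliant/non-compliant at 50%),
traditional candidates to none. Mortality from a general-population life
table applies to every living state each cycle
($q_{cycle} = 1-(1-q_{annual})^{1/2}$); surgery itself is assumed never
fatal, and the implant does not change life expectancy.

## Parameters and priors

All inputs live in one parameter table (`default_parameter_set()`), each
row a mean, 95% CI, and prior family. Where the source reports an interval
it is used verbatim; the remaining probabilistic inputs (health-state
utilities, adverse-event probabilities and disutilities, and per-block cost
multipliers with mean 1) carry an assumed ±20% interval, flagged
`ci_assumed` so the two provenances are never confused.

Priors are fitted by a one-dimensional search that **holds the mean
exactly** — beta: shape1 $= m\kappa$, shape2 $= (1-m)\kappa$, searching
over the concentration $\kappa$; gamma: scale $= m/$shape, searching over
the shape — minimising the summed squared error of the 2.5% and 97.5%
quantiles against the reported interval. This is the minimal-assumption
reading of "mean plus 95% CI". Two reported intervals deserve a warning:
the internal-failure CI (0.011–0.040 around mean 0.025) and especially the
external-failure CI (0.002–0.018 around mean 0.004) are infeasible for
*any* beta holding the reported mean — the best achievable maximum relative
quantile error is about 7% and 50% respectively. The fit keeps the mean
(which drives the base case and the draw means) and takes the least-squares
interval; the achieved quantiles are attached to each fit as the
`achieved_ci` attribute.

Random draws are **counter-keyed**: the uniform variate behind draw $k$ of
parameter $j$ depends only on (root seed, $k$, $j$), so a fixed seed is
bit-reproducible, draw $k$ is independent of whether draws $1..k-1$ were
generated, and adding a parameter does not shift the others' streams.
Parameters are drawn independently; no correlation structure is imposed.

## Synthetic inputs: mortality and the utility-norm curve

Two curves this model family needs are not part of the printed input
tables, so the package generates defensible stand-ins, both swappable for
real data via `read_life_table()` / `read_norm_curve()`:

* **Life table** — Gompertz–Makeham hazard $h(x) = a + b e^{cx}$ with
  $a = 5\times10^{-4}$, $b = 1.4\times10^{-5}$, $c = 0.10$, integrated
  exactly over each year of age. The defaults were chosen once so that life
  expectancy at the entry age 52.8 is 31.0 years, a plausible figure for
  the UK adult population; the terminal age is 110. The validation battery
  checks the table against its closed-form survival and against direct
  simulation of individual lifespans.
* **Norm curve** — the population utility norm declines linearly by 0.03
  per decade (a typical magnitude for adult HUI3 population norms), clamped
  to $[0,1]$, anchored at the entry age to baseline utility + reported norm
  decrement per candidate type: $0.410 + 0.439 = 0.849$ for traditional
  candidates and $0.494 + 0.374 = 0.868$ for marginal ones. The two printed
  utility/decrement pairs imply *different* norms at the same age; the
  package resolves this by anchoring per candidate type, which preserves
  both printed baselines exactly. Because ageing is applied as the additive
  norm difference from the entry age, only the slope — not the anchor —
  moves results, except through the cap at the norm itself.

What passing tests on these synthetic inputs shows: the machinery
(fitting, engine, accounting, uncertainty analysis) is correct and
internally consistent. What it does not show: agreement with results
computed on the real national life table and norm curve those stand-ins
replace; reproduction tolerances in `test-acceptance.R` are asserted
against the published figures with that caveat.

## Utilities

State utilities enter at their printed values — e.g. a traditional
candidate's functioning implant is worth $0.410 + 0.214 = 0.624$ — and age
with the population: $u(age) = u(entry) + norm(age) - norm(entry)$, floored
at zero and capped at the norm. Non-compliant hearing-aid users, unaided
states, and recipients who keep a faulty device unused take their
pre-implant support utility (the unaided 0.410, or the candidate baseline
for faulty-device keepers). Processor upgrades confer no utility gain.
QALYs accrue at `utility × 0.5` per six-month cycle.

## Costs

Costs come from the four-column resource tables (`default_cost_tables()`),
each item `visits × units × unit cost`, grouped into blocks that the
schedule consumes exactly once:

* pre-implant assessment £1,822 — divided by the eligibility proportion
  0.70, because every assessed candidate is costed but only the eligible
  fraction proceeds to surgery (this is the only channel through which
  eligibility can move the ICER, and the one-way analysis confirms it
  matters);
* surgery + device £5,956 + £16,964 = £22,920 at cycle 0;
* expected short-term adverse-event cost
  $\sum_i p_i c_i = £9.76$ (infection costs a GP visit plus antibiotics),
  charged once in the surgery cycle;
* year-1 programming/rehabilitation £1,435 spread over the first two
  cycles; year-2+ tuning, £328 equipment maintenance and £44 administration
  (£552/year, £276/cycle) from the second year onwards;
* processor replacement £5,270 per event; explant £4,379; re-implant
  £6,675; hearing aids £166 single / £332 pair;
* long-term vertigo: one GP visit (£31) per year for life, a deliberately
  conservative minimal reading exposed as
  `lt_vertigo_gp_visits_per_year`.

In the probabilistic analysis each block is scaled by a gamma multiplier
(mean 1, ±20%), so cost uncertainty propagates coherently and doubling all
unit costs exactly doubles every schedule entry.

**Renewal clocks.** Processor upgrades recur with a gamma-distributed
inter-event time (mean 106 months; the shape comes from the fitted
29–232-month interval, and probabilistic draws rescale the gamma so its
mean tracks the drawn mean), restarting after each replacement. The cohort
engine charges the *expected* number of upgrades per cycle from the
discrete renewal equation $u = f + u * f$, solved on a one-month internal
grid with midpoint binning and aggregated to cycles. The fine grid matters:
binning inter-event times at six-month cycle ends understates the long-run
renewal rate by half a cycle per event (~3% of upgrade spending), an error
the microsimulation cross-check exposed during development. Hearing-aid
replacement (mean lifetime 5 years) uses the same machinery: in the
comparator arm the whole cohort gets an initial pair and compliant users
replace it per renewal (policy exposed as `ha_replacement`); in the implant
arm, marginal candidates keep and replace a single contralateral aid.

## Engine conventions

* **Accrual timing.** Rewards (utilities, recurring costs) accrue on the
  occupancy *arriving* at the end of each interval, discounted at
  $(1+r)^{-k/2}$ for interval $k$; time-0 entry costs (assessment, surgery,
  initial aids) are undiscounted, and in-cycle event costs share their
  interval's discount factor. This end-of-cycle convention is pinned by an
  exact oracle: a two-state cohort with constant per-cycle death
  probability $q$, utility 1 and no discounting must yield
  $0.5\,(1-q)/q$ QALYs (a geometric series), which the engine reproduces to
  $10^{-9}$. It also makes the year-1 cost profile land on the first year
  of life with the device. A half-cycle (trapezoid) correction is available
  as `half_cycle_correction = TRUE`; the default is off, and the flag
  exists to quantify its impact (about +0.05 QALYs on the implant arm and a
  ~0.4% lower ICER, since the correction largely cancels between arms).
* **Failure hazards.** The internal (0.025) and external (0.004) failure
  probabilities are read as lifetime cumulative probabilities — they come
  from a long-run revision series — and converted to a constant per-cycle
  hazard over the cohort's remaining life expectancy at entry
  ($1-(1-p)^{1/N}$ over $N$ cycles). The literal per-cycle reading is
  available as `failure_interpretation = "per_cycle"`.
* **Numerical hygiene.** Every transition matrix is validated on
  construction (entries in $[0,1]$, rows summing to 1 within $10^{-9}$;
  the realized worst case across draws is $\sim10^{-16}$); cohort
  occupancy must stay conserved within $10^{-10}$ with monotone death
  occupancy; an invalid matrix aborts the run, and the PSA logs and
  resamples any draw that aborts (none do under the default priors, whose
  supports make rows stochastic by construction).
* **Small approximations.** Recipients in the long-term vertigo state who
  are re-implanted stay in that state and take the expected short-term
  adverse-event disutility as a one-off decrement (instead of re-entering
  the tunnel, which would lose the vertigo marker); recipients who cease
  implant use lose the vertigo marker; upgrades during the tunnel cycle are
  charged like any other device cycle. The affected occupancies are of
  order 1% and the microsimulation cross-check bounds the aggregate effect.

## Validation

`validate_model()` runs the battery every analysis should pass before its
results are read: prior round-trip (each fitted prior reproduces its mean
to $10^{-6}$), draw admissibility over repeated draws, transition row sums,
conservation and death monotonicity, a null-effect run (no utility
increment and no events ⇒ zero incremental QALYs), an extreme-mortality run
(death in the first cycle ⇒ lifetime cost collapses to the entry costs),
and the microsimulation cross-check.

The microsimulation (`simulate_individuals()`) is an independent
implementation of the same decision problem at the individual level: it
samples each adverse event, failure, and renewal clock per person (actual
gamma clocks that reset on replacement) rather than using expectations, so
agreement with the cohort engine within Monte Carlo error (asserted at 3
standard errors with 10,000 individuals) checks the cohort algebra, the
renewal expectation, and the accounting conventions simultaneously.

## Uncertainty analysis

`run_psa()` draws all parameters (common random numbers across the two arms
within a draw, for variance reduction), runs both arms, and records
per-draw incremental cost/QALY pairs. The CEAC uses the net monetary
benefit rule $P(\lambda\,\Delta E - \Delta C \ge 0)$, which remains correct
in every quadrant of the cost-effectiveness plane. Because the summary
"mean ICER" is convention-dependent, both the ratio of means and the mean
of ratios are computed and reported. `one_way()` / `tornado()` pin one
parameter at its interval limits with everything else at the mean;
`discount_scenarios()` sweeps 1.5%, 3%, 3.5% and 5%;
`convention_sweep()` evaluates all twelve combinations of the structural
flags so the sensitivity of the ICER to the open conventions is visible at
a glance.

Problem sizes: the acceptance script runs 10,000 draws per scenario (the
conventional PSA size for this model family) and a 10,000-individual
microsimulation; the test suite uses 1,000-draw and smaller smoke versions
of the same computations.

## Known limitations

* The synthetic life table and norm curve are stand-ins; absolute QALY and
  cost levels shift with survivorship, and reproduction of published
  figures inherits that uncertainty (the incremental QALYs and CEAC
  probabilities are much less sensitive than the incremental costs).
* The processor-upgrade stream is read as a renewing clock; reading it as a
  single (first-ever) upgrade would remove roughly two-thirds of the
  discounted upgrade spending, and is the leading candidate explanation for
  the gap between this implementation's incremental costs and the published
  ones.
* No parameter correlations, no carer/family utilities, no productivity or
  cognition effects, no bilateral implantation, single sex-combined
  cohort.
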
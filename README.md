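# cochleaCEA

A Markov cohort cost–utility model of unilateral cochlear implantation
(UCI) in adults with severe to profound sensorineural hearing loss,
compared against acoustic hearing aids (for "marginal" candidates who had
some benefit from aids) or against no hearing aids (for "traditional"
candidates who had none). The model takes a health-system (NHS)
perspective, a lifetime horizon with six-month cycles, 3.5% annual
discounting of costs and health outcomes, and 2018 GBP prices. It is
written for health economists and HTA analysts who want a tested, scripted,
fully reproducible version of this class of decision model rather than a
spreadsheet.

## The model

States cover the implant pathway and its comparators:

* `UCI_well` — functioning implant (utility = candidate baseline + the
  implant utility increment);
* `UCI_st_ae` — a one-cycle tunnel state for short-term surgical adverse
  events (dysgeusia, vertigo, tinnitus, wound infection), entered with the
  joint adverse-event probability;
* `UCI_lt_ae` — lifetime vertigo after surgery;
* internal device failure branches into re-implantation (with renewed
  adverse-event exposure), explantation, or keeping a faulty device unused;
  external failure into processor replacement or cessation;
* post-cessation states (hearing aid compliant / non-compliant / unaided)
  and the comparator-arm states `HA_compliant`, `HA_noncompliant`, `no_HA`;
* `death`, absorbing, driven by an age-indexed all-cause life table.

Per-cycle utilities come from HUI3-based health-state values that age with
a population utility-norm curve; costs combine one-off event costs
(assessment, surgery + device, processor replacements on a renewal clock
with mean 106 months, explants, re-implants) with recurring
programming/rehabilitation and maintenance profiles. For two strategies the
model reports discounted lifetime cost and QALYs per arm and the
incremental cost-effectiveness ratio ICER = ΔC / ΔE. Parameter uncertainty
is propagated by Monte Carlo: each parameter reported as a mean with a 95%
CI carries a beta (probabilities, utilities) or gamma (times, costs) prior
fitted by holding the mean exactly and matching the interval in least
squares; the cost-effectiveness acceptability curve (CEAC) is the share of
draws with non-negative net monetary benefit λ·ΔE − ΔC.

Two inputs this class of model needs are not part of the published input
tables and are generated synthetically (and swappably): a Gompertz–Makeham
life table calibrated to ~31 years of life expectancy at the cohort entry
age of 52.8, and a linearly declining population utility-norm curve
(0.03 utility per decade) anchored to the printed baseline utilities. See
`vignettes/cost-utility-model.Rmd` for every modelling choice and its
rationale.

## Worked example

```r
library(cochleaCEA)

mod <- uci_model()          # default inputs, synthetic life table and norms
base_case(mod, "vs_noHA")   # traditional candidates vs no hearing aid
```

```
Base case, vs_noHA (traditional candidates)
  no_HA                        cost         0  QALY   6.67
  Unilateral cochlear implant  cost     45447  QALY  10.53
  Difference                   cost     45447  QALY   3.85
  ICER: 11793 GBP per QALY gained
```

An implant adds 3.85 discounted QALYs over a lifetime at a discounted
incremental cost of £45,447, i.e. £11,793 per QALY gained — well under the
usual £20,000/QALY willingness-to-pay threshold. The probabilistic
analysis propagates all parameter priors:

```r
psa <- run_psa(mod, n = 1000, seed = 1, scenario = "vs_noHA")
psa
```

```
PSA, vs_noHA: 1000 draws (seed 1)
  mean difference: cost 49466 GBP, 3.879 QALYs
  ICER (ratio of means) 12753, (mean of ratios) 12891 GBP/QALY
  95% intervals: cost (37936, 73878), QALY (3.123, 4.728), ICER (9090, 20153)
  P(cost-effective at 20000 GBP/QALY) = 0.972
```

Every simulated draw lands in the northeast quadrant of the
cost-effectiveness plane (more effective, more costly), and the implant is
cost-effective at £20,000/QALY in 97% of draws. `plot(psa)` and
`plot(psa, "ceac")` draw the plane and the acceptability curve;
`tornado(mod)` ranks one-way parameter sensitivities;
`validate_model(mod)` runs the internal-consistency battery, including an
individual-level microsimulation cross-check of the cohort engine.

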
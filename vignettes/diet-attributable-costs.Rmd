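---
title: "Modelling diet-attributable cardiometabolic costs with cardiocost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling diet-attributable cardiometabolic costs with cardiocost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiocost)
library(dplyr)
```

`cardiocost` estimates the annual healthcare costs of cardiometabolic
disease (CMD: coronary heart disease, stroke, type 2 diabetes) that are
attributable to suboptimal intake of ten dietary factors. This vignette
is the package's own account of the model: its structure and
assumptions, the parameters that matter, what the synthetic data do and
do not emulate, and the numerical and design choices behind the
implementation.

## The estimand

The attributable cost is a counterfactual contrast. The same simulated
cohort is run twice under identical random streams: once with its
observed diet, once with intakes moved to optimal levels. The per-capita
annual attributable cost is the difference in final-cycle costs divided
by the observed run's final-cycle person-time, reported in total and
split into acute, chronic CVD, chronic diabetes, and drug components.
Using the *observed* cross-section as the denominator for both runs is a
deliberate choice: the two scenarios have different survivor sets (an
optimal diet averts deaths), so per-scenario denominators would make
stratified results inconsistent with the overall figure. With a common
denominator the person-time-weighted mean of stratum-level costs equals
the overall per-capita cost exactly, which the test suite asserts.

Because only persons *worse* than optimal are moved (better-than-optimal
intakes are left unchanged, and no benefit accrues beyond the optimum),
the estimate is conservative by construction.

## Dose–response model

Each factor `f` has a direction, an optimal level, and per-unit relative
risks for the diseases it is causally linked to. Risk is log-linear in
the intake gap — the distance from optimal in the harmful direction —
with the gap floored at zero:

$$\mathrm{RR}_{f,d}(g) = \exp\!\big(a(\mathrm{age}) \cdot \log
\mathrm{rr}_{f,d} \cdot g / u_f\big),$$

where $u_f$ is the reference unit (e.g. 100 g/day of fruit) and
$a(\mathrm{age})$ a piecewise-constant attenuation of the log relative
risk over age bands (default 1.0 at 35–44 declining to 0.4 at 75+,
reflecting the usual attenuation of relative effects with age; the
schedule is fully configurable). Factor effects combine
multiplicatively; a factor with no configured link to a disease
contributes 1. The log-linear (constant per-unit log-RR) form is the
standard comparative-risk-assessment choice when only per-unit relative
risks are available. Two consequences are tested as invariants: moving
any intake toward optimal never raises any disease risk, and the joint
attributable cost is sub-additive — at most the sum of the ten
single-factor costs — because
$1 - \prod_f (1 - x_f) \le \sum_f x_f$ for multiplicative risks.

**The bundled `default_diet_factors()` relative risks are synthetic
placeholders.** Their magnitudes are in the plausible range of published
diet–disease meta-analyses, but they are not the validated effect sizes
of any published model, and the same holds for the dollar values in
`cost_parameters()`. Headline dollar outputs under the defaults are
therefore illustrative; substantive analyses must supply their own
factor and cost tables (the configuration makes every number
replaceable).

Sodium is special-cased. By default (`sodium$pathway = "bp"`) its effect
is routed through systolic blood pressure rather than a direct relative
risk: closing the sodium gap lowers SBP by `bp_slope` mmHg per 1,000
mg/day (default 1.0, a conservative population-average value), which
lowers risk through the baseline risk function, and treated persons whom
the change moves from at-or-above to below the 140 mmHg hypertension
cutoff stop antihypertensive treatment. This pathway is what makes
sodium the only factor with a nonzero drug-cost component. A direct-RR
mode (`"rr"`) is also implemented and selectable.

## The microsimulation

Persons are simulated in yearly cycles over a 5-year horizon. Each
cycle:

1. **Risk-factor drift** — age increments; SBP and total cholesterol
   follow configurable linear drifts (defaults 0.5 mg/dL and 0.5
   mmHg/year).
2. **Baseline risk** — a Framingham-style general-CVD survival-form
   equation (sex-specific coefficients on log age, log total and HDL
   cholesterol, log SBP with separate treated/untreated terms, smoking,
   diabetes) is converted to an annual hazard. The published general-CVD
   coefficients ship as defaults and are documented substitutes for a
   calibrated policy-model risk engine; results depend on them and they
   are fully config-exposed.
3. **Event split and scaling** — the CVD hazard is split by fixed
   configurable shares (MI 0.30, angina 0.25, cardiac arrest 0.05,
   stroke 0.40; the event set is standard but shares are a modelling
   choice), each scaled by the matching diet relative risk (CHD risks
   scale MI/angina/cardiac arrest; the stroke risk scales stroke) and by
   a postacute multiplier (default 2.0) for persons with established
   CVD. Diabetes onset (logistic baseline in age, sex, BMI; no re-onset)
   and Gompertz-style background mortality complete the hazard set.
4. **Competing risks** — all hazards are resolved in one multinomial
   draw per person-year via $P(i) = h_i/H\,(1 - e^{-H})$, which is
   order-independent and keeps probabilities in $[0,1]$ under any
   relative-risk scaling. Case fatality (flat defaults: MI 0.25, stroke
   0.20, cardiac arrest 0.90) decides fatal versus nonfatal events;
   post-event states are absorbing short of death.
5. **Entrants** — a cohort of 35-year-olds (default 1.5% of the base
   cohort, growing 1%/year) joins each cycle after the first. No survey
   table describes age-35 entrants, so `population_spec_age35()` is
   synthetic: adult intake distributions with clinical values and
   disease prevalences shifted to plausible age-35 levels.

**Common random numbers.** Every stochastic draw is keyed to the master
seed and the cycle index — never to the scenario — and draws are
consumed for dead persons too, so the per-person uniform streams align
exactly across scenarios. Scenario differences are therefore not
inflated by simulation noise, and a null counterfactual gives exactly
zero attributable cost (asserted bitwise in the tests).

`fixed_event_probs` replaces the risk engine with constant annual event
probabilities; it exists for calibration and testing (it is what lets
the test suite compare the simulator against exhaustive Markov-chain
enumeration). Supplied probabilities are converted to hazards and still
scaled by diet relative risks.

## Cost accounting

Costs follow the standard acute / chronic / drug decomposition. Acute
costs book in the event's cycle (fatal events included — the
hospitalization happens either way). Chronic costs attach to person-
years: CVD-state costs begin the cycle *after* the event, because the
panel records each person's state at the start of the cycle (this is the
postacute definition; same-cycle booking is available by configuring
state costs). Diabetic person-years carry the chronic diabetes cost and
treated person-years the antihypertensive drug cost. All amounts are
inflated to 2018 USD and discounted at 3%/year with cycle 1 discounted
one year (year 0 means no discounting).

Half-cycle correction weights the first and last cycle's person-time by
0.5, on the usual argument that mid-cycle events otherwise bias
annualized figures; the weights apply uniformly to person-time costs and
to acute event costs, so the discounted total of a constant stream is
$\sum_t w_t\,c/(1.03)^t$ with $w = (0.5, 1, 1, 1, 0.5)$ — asserted to
1e-9 in the tests. Annualization divides final-cycle costs by
final-cycle person-time, so the half-cycle weight cancels and the result
is a true annual rate. Totals equal the sum of the four components
exactly at every aggregation level (person-year, overall, stratum);
this additivity is asserted, not rounded into existence — reporting
rounds per-capita dollars to integers only at display time.

## Uncertainty

95% intervals are Monte-Carlo percentile intervals over relative-risk
uncertainty: each draw perturbs every factor's relative risks
lognormally, $\exp(N(\log \mathrm{rr}, \mathrm{se}^2))$, reruns both
scenarios under the same simulation seed, and records the attributable
total. The default is 1,000 draws; the bundled acceptance script uses
200 draws at $n = 20{,}000$, which it states as its reporting choice.
Simulation-seed noise can be added by varying the seed across draws, but
relative-risk uncertainty dominates at these cohort sizes.

## The synthetic population

`generate_population()` draws independent marginals calibrated to a
national health survey's modeled-population description of adults aged
35–85: age-band shares (38.7 / 37.8 / 23.5% for 35–49 / 50–64 / 65–85,
uniform within band, since only band shares are published), sex, race,
education, and insurance shares, clinical risk-factor moments, disease-
history prevalences, and the ten intake distributions.

Intake families are chosen for right-skewed nonnegative data published
as mean/SD pairs: gamma for strictly positive nutrients (sodium),
truncated normal on $[0, 100]$ for PUFA %-energy, and zero-inflated
gamma for episodically consumed foods. For the zero-optimal factors the
point mass at zero *is* the published at-optimal share (SSBs 48.1%,
processed meats 32.1%) and is matched exactly in expectation; the
positive part is then calibrated so the *overall* mean and SD still
match the published moments. Nuts/seeds (0.30) and seafood omega-3
(0.25) also get a point mass at zero — no value is published for these,
so the defaults are a one-time realistic choice for usual-intake
distributions, and the moment calibration makes the overall mean/SD
independent of them. For protective factors with positive optima the
published at-optimal share is the *upper-tail* mass; a two-parameter
family cannot match mean, SD, and tail mass simultaneously (forcing the
nuts tail to its published share would shift the mean by roughly 2.5
g/day), so the generator matches moments exactly and lets the tail be
emergent — the moment-fit tails land close to the published shares
(e.g. PUFA ≈ 11.8% vs 11.4%).

Marginals are independent by default; a Gaussian-copula correlation
matrix across the intakes (`intake_corr`) induces dependence between
foods while preserving every marginal exactly, but no published
correlation matrix ships with the package.

What the generator does **not** emulate: dependence between diet and
demographics (diet quality correlates with education, income, and BMI
in reality, which matters for stratified results), survey design
effects, measurement-error correction of 24-hour recalls, and secular
trends. Passing tests demonstrate that the pipeline's logic is correct
under the stated marginal structure, not that the default outputs are
unbiased estimates for the real population.

Weighted resampling (`resample_weighted()`) reproduces the
survey-to-model-population step: rows are drawn with probability
proportional to `sample_weight` and the resampled table's weights reset
to 1.

## Numerical choices and degenerate inputs

- All seeds derive from a master seed plus a context label through a
  modular hash (`derive_seed()`), so module streams are independent,
  below $2^{31}$, and reproducible under any iteration order; library
  code restores the caller's RNG state.
- Intakes are truncated at the population's 99th percentile before gap
  computation, bounding the relative risks implied by long gamma tails;
  relative risks are additionally capped (default 10).
- Entrant cohort sizes round half-up; `n = 0` populations, empty event
  ledgers, and single-stratum populations are all defined and tested.
- Zero-inflation calibration falls back to an exponential-scale spread
  if the implied positive-part variance is infeasible.
- The multinomial resolution uses a single uniform against cumulative
  probabilities; category order is fixed, so results are reproducible
  across platforms.

## Problem sizes

The test suite runs the full pipeline at cohort sizes of 300–20,000 with
calibration checks at 200,000 over 20 seeds, and the Markov-oracle
comparison at 50,000 replicates; the acceptance script uses a 200,000-
person survey draw, a 20,000-person simulation cohort, and 200
Monte-Carlo draws. These sizes are the package's reporting choices;
all of them scale linearly in persons × cycles.

## Known limitations

- Heart failure, atrial fibrillation, and renal disease are outside the
  event set, as are indirect/productivity costs and intervention
  implementation costs, so attributable costs are understated relative
  to an all-consequences accounting.
- The default risk engine, case fatalities, drift regressions, effect
  sizes, and costs are documented substitutes; conclusions about
  absolute dollar magnitudes require validated inputs.
- Independent diet–demographic marginals understate between-stratum
  contrast in diet quality; the copula option only covers dependence
  among the intakes themselves.
- One multinomial draw per person-year forbids multiple distinct events
  in one cycle (e.g. MI and diabetes onset), a standard yearly-cycle
  simplification.
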
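# cardiocost

Microsimulation of the annual cardiometabolic-disease (CMD) healthcare
costs attributable to suboptimal diet.

## The problem

Coronary heart disease (CHD), stroke, and type 2 diabetes account for a
large share of US healthcare spending, and a substantial part of that
burden is driven by how far the population's diet sits from optimal
intake levels of a small set of foods and nutrients. `cardiocost`
estimates that attributable burden: it simulates the cardiovascular and
diabetes natural history of an adult cohort (ages 35–85) in yearly
cycles under two diets — the diet actually observed, and a hypothetical
counterfactual in which intakes of ten dietary factors (fruits,
vegetables, nuts/seeds, whole grains, unprocessed red meat, processed
meat, sugar-sweetened beverages, polyunsaturated fats, seafood omega-3
fats, sodium) are moved to their optimal levels — and prices the
difference.

The package is aimed at health-economics and nutrition-policy modellers
who want a fully testable, self-contained version of this pipeline: a
calibrated synthetic-population generator stands in for the survey
extract, so every stage runs (and is tested) without external data.

## The model

For each person *i*, dietary factor *f*, and disease *d* ∈ {CHD, stroke,
diabetes}, risk follows a log-linear dose–response in the **intake gap**
— the distance from the optimal level in the harmful direction, with no
extra benefit beyond optimal:

    gap_f(x)  = max(0, optimal_f − x)   (protective factor)
              = max(0, x − optimal_f)   (harmful factor)

    RR_{f,d}(gap) = exp( a(age) · log(rr_{f,d}) · gap / unit_f ),

where `rr_{f,d}` is the per-unit relative risk and `a(age)` an age-band
attenuation of the log effect. Factor effects combine multiplicatively.
Each cycle, a Framingham-style general-CVD risk function gives every
person's baseline annual event hazard, split into MI / angina / cardiac
arrest / stroke; diet relative risks scale the matching hazards, and
competing events (including diabetes onset and background mortality) are
resolved by a single multinomial draw per person-year. Events carry
acute hospitalization costs; post-event states and diabetes carry annual
chronic costs; treated hypertension carries drug costs. Costs are
discounted at 3 %/year with half-cycle correction over a 5-year horizon
with entrant cohorts of 35-year-olds, and the attributable cost is the
observed-minus-counterfactual difference in final-cycle costs per
observed person-year, scaled nationally and allocated to ultimate
cost-bearers (households / government / third parties). Monte-Carlo 95 %
intervals propagate lognormal relative-risk uncertainty under common
random numbers.

The bundled relative risks and dollar costs are documented synthetic
placeholders of realistic magnitude; substantive estimates require
supplying validated inputs via the configuration.

## Worked example

```r
library(cardiocost)

pop <- generate_population(population_spec(), n = 20000, seed = 2)
mean(pop$intake_ssb == 0)      # 0.476 — share already at the SSB optimum
mean(pop$intake_sodium)        # 3481  — mg/day, matching the 3481.5 target

sweep <- per_factor_sweep(pop, seed = 5)
glance(sweep)
#> # A tibble: 1 × 5
#>       n horizon combined_total single_factor_sum n_factors
#>   <int>   <dbl>          <dbl>             <dbl>     <int>
#> 1 20000       5           341.              438.        10
```

`combined_total` is the per-capita annual CMD cost attributable to all
ten factors jointly (here $341/person/year under the synthetic default
inputs); `single_factor_sum` adds up the ten single-factor
counterfactuals and exceeds the joint cost because the factors' benefits
are not independent (multiplicative risks make the joint burden
sub-additive). `tidy(sweep)` breaks every scenario into acute, chronic
CVD, chronic diabetes, and drug components, and `autoplot(sweep)` draws
the stacked per-factor chart. `national_total(341, 167.4e6)` scales the
per-capita figure to the represented adult population, and
`bearer_allocation()` splits costs by who ultimately pays.

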
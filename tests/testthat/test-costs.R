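test_that("discounting and inflation follow their closed forms", {
  expect_equal(discount(100, 0), 100)
  expect_equal(discount(100, 1, 0.03), 100 / 1.03)
  expect_equal(discount(100, 1, 0.03), 97.0874, tolerance = 1e-6)
  expect_equal(discount(c(50, 100), c(2, 3), 0), c(50, 100))
  expect_error(discount(100, 1, -0.01), "negative")

  infl <- tibble::tibble(year = c(2015, 2018), multiplier = c(1.10, 1))
  expect_equal(inflate(100, 2018, infl), 100)
  expect_equal(inflate(100, 2015, infl), 110)
  # round trip with the reciprocal multiplier
  back <- tibble::tibble(year = 2015, multiplier = 1 / 1.10)
  expect_equal(inflate(inflate(100, 2015, infl), 2015, back), 100,
               tolerance = 1e-9)
  expect_error(inflate(100, 1999, infl), "1999")
})

test_that("acute costs book in the event cycle at that cycle's discount", {
  one <- toy_person(1)
  params <- cost_parameters(acute = c(mi = 20000, angina = 0, stroke = 0,
                                      cardiac_arrest = 0),
                            chronic_cvd = c(angina = 0, post_mi = 0,
                                            post_stroke = 0,
                                            post_mi_and_stroke = 0),
                            chronic_diabetes = 0, drug = c(antihypertensive = 0))
  # force one nonfatal MI in cycle 1; no half-cycle so the full acute
  # cost lands at one year of discounting: 20000 / 1.03
  cfg <- quiet_config(fixed = c(mi = 0), half_cycle = FALSE, horizon = 1)
  cfg$fixed_event_probs <- c(mi = 1 - 1e-15)
  cfg$case_fatality <- c(mi = 0, angina = 0, stroke = 0, cardiac_arrest = 0)
  sim <- run_microsim(one, scenario_observed(toy_factors()$factor),
                      toy_factors(), cfg, seed = 1)
  expect_equal(sim$events$event_type, "mi")
  costs <- accumulate_costs(sim, params)
  expect_equal(sum(costs$person_year$acute), 20000 / 1.03,
               tolerance = 1e-9)
  expect_equal(sum(costs$person_year$total), 20000 / 1.03,
               tolerance = 1e-9)
})

test_that("chronic person-years carry half-cycle weights", {
  # one diabetic person alive 5 years, chronic diabetes 1,000/year,
  # no discounting: weights 0.5+1+1+1+0.5 give 4,000
  one <- toy_person(1, diabetes = TRUE)
  params <- cost_parameters(acute = c(mi = 0, angina = 0, stroke = 0,
                                      cardiac_arrest = 0),
                            chronic_cvd = c(angina = 0, post_mi = 0,
                                            post_stroke = 0,
                                            post_mi_and_stroke = 0),
                            chronic_diabetes = 1000,
                            drug = c(antihypertensive = 0),
                            discount_rate = 0)
  sim <- run_microsim(one, scenario_observed(toy_factors()$factor),
                      toy_factors(), quiet_config(), seed = 1)
  costs <- accumulate_costs(sim, params)
  expect_equal(sum(costs$person_year$chronic_diabetes), 4000)
  # with discounting the same stream matches sum(w_t * c / 1.03^t)
  params3 <- params; params3$discount_rate <- 0.03
  costs3 <- accumulate_costs(sim, params3)
  w <- c(0.5, 1, 1, 1, 0.5)
  expect_equal(sum(costs3$person_year$chronic_diabetes),
               sum(w * 1000 / 1.03^(1:5)), tolerance = 1e-9)
})

test_that("chronic CVD costs start the cycle after the event", {
  one <- toy_person(1)
  cfg <- quiet_config()
  cfg$fixed_event_probs <- c(mi = 1 - 1e-15)
  cfg$case_fatality <- c(mi = 0, angina = 0, stroke = 0, cardiac_arrest = 0)
  params <- cost_parameters(acute = c(mi = 0, angina = 0, stroke = 0,
                                      cardiac_arrest = 0),
                            chronic_cvd = c(angina = 0, post_mi = 100,
                                            post_stroke = 0,
                                            post_mi_and_stroke = 0),
                            chronic_diabetes = 0,
                            drug = c(antihypertensive = 0),
                            discount_rate = 0)
  sim <- run_microsim(one, scenario_observed(toy_factors()$factor),
                      toy_factors(), cfg, seed = 1)
  costs <- accumulate_costs(sim, params)
  by_cycle <- costs$person_year
  # MI happens in cycle 1; the post-MI state (and its cost) appears from
  # cycle 2 on: weights 1+1+1+0.5
  expect_equal(by_cycle$chronic_cvd[by_cycle$cycle_year == 1], 0)
  expect_equal(sum(by_cycle$chronic_cvd), 100 * 3.5)
})

test_that("total equals the sum of components at every aggregation level", {
  pop <- generate_population(n = 2000, seed = 24)
  sim <- run_microsim(pop, scenario_observed(), seed = 25)
  costs <- accumulate_costs(sim)
  py <- costs$person_year
  expect_equal(py$total,
               py$acute + py$chronic_cvd + py$chronic_diabetes + py$drug)
  ann <- annualize_costs(costs, sim)
  expect_equal(ann$total,
               ann$acute + ann$chronic_cvd + ann$chronic_diabetes + ann$drug)
  ann_sex <- annualize_costs(costs, sim, by = "sex")
  expect_equal(ann_sex$total,
               ann_sex$acute + ann_sex$chronic_cvd +
                 ann_sex$chronic_diabetes + ann_sex$drug)
  expect_true(all(py[c("acute", "chronic_cvd", "chronic_diabetes",
                       "drug")] >= 0))
  expect_error(accumulate_costs(
    sim, cost_parameters(acute = c(mi = 100))), "angina")
})

test_that("positive discounting strictly lowers later costs", {
  pop <- generate_population(n = 500, seed = 26)
  sim <- run_microsim(pop, scenario_observed(), seed = 27)
  disc <- accumulate_costs(sim, cost_parameters(discount_rate = 0.03))
  undisc <- accumulate_costs(sim, cost_parameters(discount_rate = 0))
  expect_lt(sum(disc$person_year$total), sum(undisc$person_year$total))
})

test_that("annualization divides final-cycle costs by final person-time", {
  # uniform chronic cost: per-capita equals the annual rate exactly,
  # with the half-cycle weight cancelling
  n <- 50
  many <- toy_person(n, diabetes = TRUE)
  params <- cost_parameters(acute = c(mi = 0, angina = 0, stroke = 0,
                                      cardiac_arrest = 0),
                            chronic_cvd = c(angina = 0, post_mi = 0,
                                            post_stroke = 0,
                                            post_mi_and_stroke = 0),
                            chronic_diabetes = 301,
                            drug = c(antihypertensive = 0),
                            discount_rate = 0)
  sim <- run_microsim(many, scenario_observed(toy_factors()$factor),
                      toy_factors(), quiet_config(), seed = 1)
  ann <- annualize_costs(accumulate_costs(sim, params), sim)
  expect_equal(ann$total, 301)
  expect_equal(ann$n_alive, n)
})
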
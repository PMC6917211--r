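# Shared fixtures: toy factor tables, quiet configurations, and an
# all-optimal entrant spec, all built in code at test time.

# two-factor table with clean round numbers for arithmetic checks
toy_factors <- function() {
  tibble::tibble(
    factor = c("toy_a", "toy_b"),
    unit = c("g/day", "servings/day"),
    direction = c("protective", "harmful"),
    optimal = c(10, 0),
    unit_size = c(1, 1),
    rr_chd = c(1.2, 1.5),
    rr_stroke = c(1.0, 1.0),
    rr_diabetes = c(1.0, 1.3),
    se_chd = c(0.05, 0.05),
    se_stroke = c(0, 0),
    se_diabetes = c(0, 0.05)
  )
}

# minimal person table with explicit values; intakes given per toy factor
toy_person <- function(n = 1, intake_a = 10, intake_b = 0, age = 50,
                       diabetes = FALSE, htn_treated = FALSE,
                       history_mi = FALSE, history_stroke = FALSE,
                       history_angina = FALSE) {
  tibble::tibble(
    person_id = seq_len(n),
    sex = factor(rep("male", n), levels = c("male", "female")),
    age = age,
    race = "white", education = "hs", insurance = "private",
    bmi = 28, sbp = 120, total_chol = 200, hdl = 50,
    smoker = FALSE, diabetes = diabetes, htn_treated = htn_treated,
    history_angina = history_angina, history_mi = history_mi,
    history_stroke = history_stroke,
    sample_weight = 1,
    intake_toy_a = intake_a, intake_toy_b = intake_b
  )
}

# configuration with no entrants and every stochastic event switched off
# unless probabilities are supplied; sodium routed as direct RR so toy
# tables without a sodium column work unchanged
quiet_config <- function(fixed = c(mi = 0), ...) {
  sim_config(entrant_frac = 0, fixed_event_probs = fixed,
             sodium = list(pathway = "rr"), cap_quantile = NULL, ...)
}

# age-35 entrant spec whose intakes are all exactly optimal
optimal_spec35 <- function(factors = default_diet_factors()) {
  s35 <- population_spec_age35()
  s35$intakes$mean <- factors$optimal[match(s35$intakes$factor,
                                            factors$factor)]
  s35$intakes$sd <- 0
  s35$intakes$zero_mass <- 0
  s35$intakes$family <- "gamma"
  s35
}
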
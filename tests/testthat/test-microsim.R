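test_that("disease history seeds the corresponding health states", {
  t <- toy_person(4)
  t$history_mi <- c(FALSE, TRUE, FALSE, TRUE)
  t$history_stroke <- c(FALSE, FALSE, TRUE, TRUE)
  t$history_angina <- c(FALSE, FALSE, FALSE, FALSE)
  st <- seed_states(t)
  expect_equal(as.character(st$state),
               c("well", "post_mi", "post_stroke", "post_mi_and_stroke"))

  a <- toy_person(1, history_angina = TRUE)
  expect_equal(as.character(seed_states(a)$state), "angina")

  d <- toy_person(1, diabetes = TRUE)
  expect_true(seed_states(d)$diabetes)
})

test_that("state seeding matches configured history prevalences", {
  n <- 100000
  pop <- generate_population(n = n, seed = 13)
  st <- seed_states(pop)
  share <- function(s) mean(st$state == s)
  se <- function(p) sqrt(p * (1 - p) / n)
  # angina share excludes those promoted to post-MI/stroke states:
  # P(angina alone) = 0.026 * (1 - 0.043) * (1 - 0.033)
  p_ang <- 0.026 * (1 - 0.043) * (1 - 0.033)
  expect_lt(abs(share("angina") - p_ang), 3 * se(p_ang))
  p_mi <- 0.043 * (1 - 0.033)
  expect_lt(abs(share("post_mi") - p_mi), 3 * se(p_mi))
  p_both <- 0.043 * 0.033
  expect_lt(abs(share("post_mi_and_stroke") - p_both), 3 * se(p_both))
})

test_that("risk-factor drift is linear and age always increments", {
  p <- toy_person(1)
  zero <- update_risk_factors(p, drift = c(sbp = 0, total_chol = 0, hdl = 0))
  expect_equal(zero$age, p$age + 1)
  expect_equal(zero$sbp, p$sbp)

  one <- update_risk_factors(p, drift = c(sbp = 0.5))
  expect_equal(one$sbp, 120.5)
  ten <- p
  for (i in 1:10) ten <- update_risk_factors(ten, drift = c(sbp = 0.5))
  expect_equal(ten$sbp, 125.0)
  expect_equal(ten$age, p$age + 10)
})

test_that("diet relative risks scale event hazards as configured", {
  cfg <- quiet_config(fixed = c(mi = 0.005))
  p <- toy_person(1)
  st <- seed_states(p)
  base <- annual_event_probs(p, st, list(chd = 1), cfg)
  dbl <- annual_event_probs(p, st, list(chd = 2), cfg)
  # hazard-scale doubling for a small baseline hazard
  expect_lt(abs(dbl$p_mi - 2 * base$p_mi) / (2 * base$p_mi), 0.01)
  h <- -log(1 - 0.005)
  expect_equal(dbl$p_mi, 1 - exp(-2 * h), tolerance = 1e-12)
  # RR = 1 leaves probabilities unchanged
  expect_equal(annual_event_probs(p, st, list(chd = 1, stroke = 1,
                                              diabetes = 1), cfg),
               base)
  expect_error(annual_event_probs(p, st, list(chd = -1), cfg), "negative")
})

test_that("diabetes does not re-onset and probabilities stay in [0, 1]", {
  cfg <- quiet_config(fixed = c(diabetes_onset = 0.2))
  p <- toy_person(2, diabetes = c(TRUE, FALSE))
  st <- seed_states(p)
  probs <- annual_event_probs(p, st, list(diabetes = 1), cfg)
  expect_equal(probs$p_diabetes_onset[1], 0)
  expect_gt(probs$p_diabetes_onset[2], 0)

  # extreme RR scaling cannot push the row sum past 1
  cfg2 <- quiet_config(fixed = c(mi = 0.5, stroke = 0.5, other_death = 0.3))
  probs2 <- annual_event_probs(p, st, list(chd = 50, stroke = 50), cfg2)
  m <- as.matrix(probs2)
  expect_true(all(m >= 0 & m <= 1))
  expect_true(all(rowSums(m) <= 1 + 1e-12))
})

test_that("step_year resolves events, fatality, and transitions", {
  p <- toy_person(3)
  st <- seed_states(p)
  zero <- tibble::tibble(p_mi = 0, p_angina = 0, p_stroke = 0,
                         p_cardiac_arrest = 0, p_diabetes_onset = 0,
                         p_other_death = 0)[rep(1, 3), ]
  out <- step_year(st, zero, runif(3), runif(3))
  expect_equal(nrow(out$events), 0)
  expect_equal(as.character(out$states$state), rep("well", 3))

  # forced MI with case fatality 1 kills in the same cycle
  mi <- zero; mi$p_mi <- 1
  out2 <- step_year(st, mi, runif(3), runif(3),
                    case_fatality = c(mi = 1, angina = 0, stroke = 0,
                                      cardiac_arrest = 0))
  expect_equal(as.character(out2$states$state), rep("dead_cvd", 3))
  expect_true(all(out2$events$fatal[out2$events$event_type == "mi"]))
  expect_true("cvd_death" %in% out2$events$event_type)

  # forced nonfatal stroke on a post-MI person gives the combined state
  st3 <- st; st3$state[1] <- factor("post_mi", levels = levels(st$state))
  strk <- zero; strk$p_stroke <- 1
  out3 <- step_year(st3, strk, runif(3), runif(3),
                    case_fatality = c(mi = 0, angina = 0, stroke = 0,
                                      cardiac_arrest = 0))
  expect_equal(as.character(out3$states$state[1]), "post_mi_and_stroke")
  expect_equal(as.character(out3$states$state[2]), "post_stroke")
})

test_that("dead persons are absorbing and the population is conserved", {
  pop <- generate_population(n = 2000, seed = 14)
  cfg <- sim_config(entrant_frac = 0,
                    fixed_event_probs = c(mi = 0.1, other_death = 0.05),
                    sodium = list(pathway = "rr"))
  sim <- run_microsim(pop, scenario_observed(), config = cfg, seed = 15)
  # each person appears at most once per cycle; alive set shrinks only
  counts <- dplyr::count(sim$panel, person_id, cycle_year)
  expect_true(all(counts$n == 1))
  deaths <- sim$events[sim$events$event_type %in%
                         c("cvd_death", "other_death"), ]
  expect_equal(anyDuplicated(deaths$person_id), 0)
  for (d in seq_len(nrow(deaths))) {
    later <- sim$panel$person_id == deaths$person_id[d] &
      sim$panel$cycle_year > deaths$cycle_year[d]
    expect_equal(sum(later), 0)
  }
})

test_that("first-event fraction matches the closed form", {
  n <- 50000
  pop <- generate_population(n = n, seed = 16)
  cfg <- sim_config(entrant_frac = 0, fixed_event_probs = c(mi = 0.1),
                    sodium = list(pathway = "rr"),
                    case_fatality = c(mi = 0, angina = 0, stroke = 0,
                                      cardiac_arrest = 0))
  # optimal scenario zeroes every intake gap, so all diet RRs are 1 and
  # the fixed per-cycle MI probability applies unscaled
  sim <- run_microsim(pop, scenario_optimal(), config = cfg, seed = 17)
  hit <- length(unique(sim$events$person_id[sim$events$event_type == "mi"]))
  p <- 1 - 0.9^5
  expect_lt(abs(hit / n - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("runs are seed-deterministic with half-cycle person-time", {
  pop <- generate_population(n = 300, seed = 18)
  a <- run_microsim(pop, scenario_observed(), seed = 19)
  b <- run_microsim(pop, scenario_observed(), seed = 19)
  expect_identical(a$events, b$events)
  expect_identical(a$panel, b$panel)

  # one person, zero risks: 5 person-years, 4.0 with half-cycle weights
  one <- toy_person(1)
  sim1 <- run_microsim(one, scenario_observed(toy_factors()$factor),
                       toy_factors(), quiet_config(), seed = 1)
  expect_equal(nrow(sim1$events), 0)
  expect_equal(nrow(sim1$panel), 5)
  expect_equal(sum(sim1$panel$weight), 4.0)
  expect_error(run_microsim(one, config = sim_config(horizon = 0)),
               "horizon")
})

test_that("raising a diet RR never lowers cumulative events under CRN", {
  pop <- generate_population(n = 5000, seed = 20)
  f <- default_diet_factors()
  worse <- f
  worse$rr_chd <- pmax(worse$rr_chd, 1.3)
  cfg <- sim_config(entrant_frac = 0)
  base <- run_microsim(pop, scenario_observed(), f, cfg, seed = 21)
  high <- run_microsim(pop, scenario_observed(), worse, cfg, seed = 21)
  n_chd <- function(s) sum(s$events$event_type %in%
                             c("mi", "angina", "cardiac_arrest"))
  expect_gte(n_chd(high), n_chd(base))
})

test_that("entrant cohorts join at 35 and grow the population", {
  pop <- generate_population(n = 1000, seed = 22)
  cfg <- sim_config(entrant_frac = 0.1, growth_rate = 0.01,
                    fixed_event_probs = c(mi = 0),
                    sodium = list(pathway = "rr"))
  sim <- run_microsim(pop, scenario_observed(), config = cfg, seed = 23)
  expect_equal(nrow(sim$population), 1000 + sum(sapply(0:3, function(y)
    entrant_size(100, 0.01, y))))
  ent <- sim$panel[sim$panel$person_id > 1000, ]
  first <- dplyr::summarise(dplyr::group_by(ent, person_id),
                            age0 = min(age))
  expect_true(all(first$age0 == 35))
})
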
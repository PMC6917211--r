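# Counterfactual attribution: observed-diet minus optimal-diet costs, per
# factor and combined, with national scaling, stratified reporting,
# Monte-Carlo confidence intervals over relative-risk uncertainty, and
# allocation of costs to ultimate cost-bearers.

COST_COMPONENTS <- c("acute", "chronic_cvd", "chronic_diabetes", "drug")

# per-person cost rows of the final cross-sectional cycle
final_cost_rows <- function(sim, params) {
  costs <- accumulate_costs(sim, params)
  filter(costs$person_year, .data$cycle_year == max(.data$cycle_year))
}

# component totals by label (labels: named character vector person_id ->
# stratum; NULL collapses everything to one group)
sum_components <- function(rows, labels) {
  lab <- if (is.null(labels)) {
    rep("all", nrow(rows))
  } else {
    unname(labels[as.character(rows$person_id)])
  }
  rows |>
    mutate(.lab = lab) |>
    group_by(.data$.lab) |>
    summarise(across(dplyr::all_of(COST_COMPONENTS), sum), .groups = "drop")
}

# core attribution: observed minus counterfactual final-cycle totals, both
# divided by the OBSERVED run's final-cycle person-time. The common
# denominator makes the person-time-weighted mean of stratum values equal
# the overall value exactly.
attrib_components <- function(sim_obs, obs_rows, sim_cf, params,
                              labels = NULL) {
  H <- sim_obs$config$horizon
  fp <- filter(sim_obs$panel, .data$cycle_year == H)
  lab <- if (is.null(labels)) {
    rep("all", nrow(fp))
  } else {
    unname(labels[as.character(fp$person_id)])
  }
  denom <- tibble(.lab = lab, weight = fp$weight) |>
    group_by(.data$.lab) |>
    summarise(n_alive = dplyr::n(), person_time = sum(.data$weight),
              .groups = "drop")
  cf_rows <- final_cost_rows(sim_cf, params)
  obs_sum <- sum_components(obs_rows, labels)
  cf_sum <- sum_components(cf_rows, labels)
  out <- denom |>
    left_join(obs_sum, by = ".lab") |>
    left_join(cf_sum, by = ".lab", suffix = c("", "_cf"))
  for (cc in COST_COMPONENTS) {
    out[[cc]] <- (tidyr::replace_na(out[[cc]], 0) -
                    tidyr::replace_na(out[[paste0(cc, "_cf")]], 0)) /
      out$person_time
  }
  out |>
    mutate(total = .data$acute + .data$chronic_cvd +
             .data$chronic_diabetes + .data$drug) |>
    select(".lab", dplyr::all_of(COST_COMPONENTS), "total", "n_alive",
           "person_time")
}

#' Attributable cost between two runs
#'
#' Per-capita annual attributable cost: the observed-diet run's final-cycle
#' cost components minus the counterfactual's, divided by the observed
#' run's final-cycle person-time. The two runs must share the population,
#' configuration, and seed (common random numbers), so the difference
#' reflects the diet change alone; the observed cross-section is the
#' per-capita denominator for both runs.
#'
#' @param sim_observed,sim_counterfactual `"cmd_sim"` runs on the same
#'   population with the same seed.
#' @param params A [cost_parameters()].
#' @return A one-row tibble: `acute`, `chronic_cvd`, `chronic_diabetes`,
#'   `drug`, `total` (USD/person/year, observed minus counterfactual).
#' @export
attributable_cost <- function(sim_observed, sim_counterfactual,
                              params = cost_parameters()) {
  stopifnot(inherits(sim_observed, "cmd_sim"),
            inherits(sim_counterfactual, "cmd_sim"))
  if (sim_observed$n_base != sim_counterfactual$n_base ||
      !identical(sim_observed$seed, sim_counterfactual$seed)) {
    abort("attributable_cost: runs must share population and seed")
  }
  obs_rows <- final_cost_rows(sim_observed, params)
  attrib_components(sim_observed, obs_rows, sim_counterfactual, params) |>
    select(dplyr::all_of(COST_COMPONENTS), "total")
}

#' Single-factor and combined attributable-cost sweep
#'
#' Runs the observed-diet scenario once, then one counterfactual per
#' dietary factor (that factor set to optimal, others observed) and one
#' all-factors-optimal counterfactual, all under common random numbers.
#' Reports each scenario's per-capita attributable components and, for the
#' single factors, their share of the combined (all-optimal) cost. With
#' multiplicative relative risks the single-factor costs generally sum to
#' more than the combined cost (the factors' benefits are not independent),
#' so shares can exceed 100% in total.
#'
#' @param table Person table.
#' @param factors Diet-factor table.
#' @param config A [sim_config()].
#' @param params A [cost_parameters()].
#' @param seed Master seed shared by every run (common random numbers).
#' @return An object of class `"cmd_attribution"`: tibble with one row per
#'   scenario (`scenario`, `acute`, `chronic_cvd`, `chronic_diabetes`,
#'   `drug`, `total`, `share_of_combined`), carrying the run metadata as
#'   attributes.
#' @export
per_factor_sweep <- function(table, factors = default_diet_factors(),
                             config = sim_config(),
                             params = cost_parameters(), seed = 1) {
  if (nrow(factors) == 0) abort("per_factor_sweep: no factors")
  sim_obs <- run_microsim(table, scenario_observed(factors$factor),
                          factors, config, seed)
  obs_rows <- final_cost_rows(sim_obs, params)
  one <- function(scn, label) {
    sim_cf <- run_microsim(table, scn, factors, config, seed)
    attrib_components(sim_obs, obs_rows, sim_cf, params) |>
      select(dplyr::all_of(COST_COMPONENTS), "total") |>
      mutate(scenario = label, .before = 1)
  }
  rows <- purrr::map_dfr(factors$factor,
                         function(f) one(scenario_optimal(f), f))
  combined <- one(scenario_optimal(factors$factor), "combined")
  out <- bind_rows(rows, combined) |>
    mutate(share_of_combined = ifelse(
      combined$total > 0, .data$total / combined$total, NA_real_))
  out$share_of_combined[out$scenario == "combined"] <- 1
  structure(out, class = c("cmd_attribution", class(out)),
            n = nrow(table), seed = seed, horizon = config$horizon)
}

#' National total from a per-capita cost
#'
#' @param per_capita USD per person per year.
#' @param population_size Number of adults represented.
#' @return USD per year.
#' @examples
#' national_total(301, 167.4e6) / 1e9 # ~50.4 billion
#' @export
national_total <- function(per_capita, population_size) {
  if (any(population_size <= 0)) {
    abort("national_total: population_size must be > 0")
  }
  per_capita * population_size
}

#' Share of a total expressed as a percentage
#'
#' @param attributable Attributable cost (same units as `total_direct`).
#' @param total_direct Total direct cost; must be positive.
#' @return `100 * attributable / total_direct`.
#' @examples
#' proportion_of_total(50.4, 276.3) # 18.2% of direct cardiometabolic cost
#' @export
proportion_of_total <- function(attributable, total_direct) {
  if (any(total_direct <= 0)) {
    abort("proportion_of_total: total_direct must be > 0")
  }
  100 * attributable / total_direct
}

# final-cycle age and BMI bands used for stratified reporting
stratum_variable <- function(sim, by) {
  pop <- sim$population
  switch(by,
    sex = , race = , education = , insurance = {
      setNames(as.character(pop[[by]]), pop$person_id)
    },
    age_band = {
      br <- cut(pop$age, breaks = c(-Inf, 49, 64, Inf),
                labels = c("35-49", "50-64", "65+"))
      setNames(as.character(br), pop$person_id)
    },
    bmi_band = {
      br <- cut(pop$bmi, breaks = c(-Inf, 30 - 1e-12, Inf),
                labels = c("<30", ">=30"))
      setNames(as.character(br), pop$person_id)
    },
    abort(paste0("stratify_costs: unknown stratifier '", by, "'"))
  )
}

#' Stratified attributable costs
#'
#' Per-capita attributable components within strata of the final
#' cross-sectional cycle: sex, age band (35-49 / 50-64 / 65+ at the final
#' cycle), race, education, BMI band (<30 / >=30), or insurance. Because
#' the per-capita denominator is the observed run's stratum person-time,
#' the person-time-weighted mean of the stratum values equals the overall
#' per-capita value exactly.
#'
#' @param sim_observed,sim_counterfactual Matched `"cmd_sim"` runs.
#' @param params A [cost_parameters()].
#' @param by One of `"sex"`, `"age_band"`, `"race"`, `"education"`,
#'   `"bmi_band"`, `"insurance"`.
#' @return A tibble: `stratum`, components, `total`, `n_alive`,
#'   `person_time`.
#' @export
stratify_costs <- function(sim_observed, sim_counterfactual,
                           params = cost_parameters(), by = "sex") {
  lab <- stratum_variable(sim_observed, by)
  obs_rows <- final_cost_rows(sim_observed, params)
  attrib_components(sim_observed, obs_rows, sim_counterfactual, params,
                    labels = lab) |>
    rename(stratum = ".lab")
}

#' Default ultimate cost-bearer mix
#'
#' Shares of each insurance category's healthcare costs borne by
#' households, the government, and third parties. Government shares for
#' Medicare (70.3%), Medicaid (95.2%), dual-eligible (93.2%), and other
#' government (59.1%) match the published summary of payment flows; the
#' household/third-party split of the remainder, and the private and
#' no-coverage rows, are synthetic defaults.
#'
#' @return A tibble: `insurance`, `household`, `government`,
#'   `third_party`; rows sum to 1.
#' @export
default_payer_mix <- function() {
  tibble(
    insurance  = c("private", "medicare", "medicaid", "dual",
                   "other_gov", "none"),
    household   = c(0.29, 0.170, 0.030, 0.045, 0.220, 0.55),
    government  = c(0.04, 0.703, 0.952, 0.932, 0.591, 0.10),
    third_party = c(0.67, 0.127, 0.018, 0.023, 0.189, 0.35)
  )
}

#' Allocate costs to ultimate cost-bearers
#'
#' Splits each insurance category's costs by its payer-mix row
#' (household / government / third party). Totals are conserved.
#'
#' @param costs_by_insurance Tibble with columns `insurance` and `cost`.
#' @param mix A payer-mix tibble ([default_payer_mix()]); rows must sum
#'   to 1 within 1e-9.
#' @return A tibble: `insurance`, `household`, `government`,
#'   `third_party`, `cost`.
#' @export
bearer_allocation <- function(costs_by_insurance,
                              mix = default_payer_mix()) {
  shares <- as.matrix(mix[, c("household", "government", "third_party")])
  if (any(shares < 0 | shares > 1)) {
    abort("bearer_allocation: payer-mix entries must lie in [0, 1]")
  }
  bad <- abs(rowSums(shares) - 1) > 1e-9
  if (any(bad)) {
    abort(paste0("bearer_allocation: payer-mix row(s) not summing to 1: ",
                 paste(mix$insurance[bad], collapse = ", ")))
  }
  missing <- setdiff(costs_by_insurance$insurance, mix$insurance)
  if (length(missing) > 0) {
    abort(paste0("bearer_allocation: no payer-mix row for: ",
                 paste(missing, collapse = ", ")))
  }
  left_join(costs_by_insurance, mix, by = "insurance") |>
    mutate(household = .data$household * .data$cost,
           government = .data$government * .data$cost,
           third_party = .data$third_party * .data$cost) |>
    select("insurance", "household", "government", "third_party", "cost")
}

#' Percentile confidence interval from Monte-Carlo draws
#'
#' 2.5th and 97.5th percentiles (linear-interpolation quantiles) of a
#' vector of draws.
#'
#' @param draws Numeric vector of at least 2 draws.
#' @return Named numeric vector `c(lo, hi)`.
#' @examples
#' ci_from_draws(1:100) # c(lo = 3.475, hi = 97.525)
#' @export
ci_from_draws <- function(draws) {
  if (length(draws) < 2) abort("ci_from_draws: need at least 2 draws")
  q <- quantile(draws, c(0.025, 0.975), names = FALSE, type = 7)
  c(lo = q[1], hi = q[2])
}

#' Monte-Carlo confidence interval for the combined attributable cost
#'
#' Propagates relative-risk uncertainty: for each draw the factor table's
#' relative risks are perturbed lognormally ([draw_rr_set()]), the observed
#' and all-optimal runs are recomputed under common random numbers (the
#' simulation seed is held fixed across draws), and the per-capita total
#' attributable cost recorded. Returns percentile 95% bounds.
#'
#' @param table Person table.
#' @param factors Diet-factor table with `se_*` columns.
#' @param config A [sim_config()].
#' @param params A [cost_parameters()].
#' @param n_draws Number of Monte-Carlo draws (default 1,000; large
#'   cohorts may warrant fewer draws for a fixed compute budget).
#' @param seed Master seed (fixes both the simulation stream and the
#'   relative-risk draws).
#' @return A list: `point` (per-capita total at the point-estimate RRs),
#'   `lo`, `hi`, `draws` (the draw vector).
#' @export
attribution_ci <- function(table, factors = default_diet_factors(),
                           config = sim_config(),
                           params = cost_parameters(),
                           n_draws = 1000, seed = 1) {
  one_total <- function(fac) {
    sim_obs <- run_microsim(table, scenario_observed(fac$factor), fac,
                            config, seed)
    sim_cf <- run_microsim(table, scenario_optimal(fac$factor), fac,
                           config, seed)
    attributable_cost(sim_obs, sim_cf, params)$total
  }
  point <- one_total(factors)
  draws <- purrr::map_dbl(seq_len(n_draws), function(d) {
    one_total(draw_rr_set(factors, seed = derive_seed(seed, "ci", d)))
  })
  ci <- ci_from_draws(draws)
  list(point = point, lo = ci[["lo"]], hi = ci[["hi"]], draws = draws)
}
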
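# Person-level cardiovascular/diabetes natural-history simulation in yearly
# cycles: Framingham-style baseline event risk, hazard-scale diet relative
# risks, competing-risk resolution by a single draw per person-cycle,
# entrant cohorts of 35-year-olds, and half-cycle person-time weighting.

CVD_STATES <- c("well", "angina", "post_mi", "post_stroke",
                "post_mi_and_stroke", "dead_cvd", "dead_other")
EVENT_TYPES <- c("mi", "angina", "stroke", "cardiac_arrest",
                 "diabetes_onset", "cvd_death", "other_death")

#' Simulation configuration
#'
#' All tunable parameters of the microsimulation. Defaults: 5-year horizon
#' with half-cycle correction, 3% discount rate (consumed by the cost
#' engine), 1%/year population growth for entrant cohorts, Framingham
#' general-CVD baseline risk coefficients (published survival-form equation,
#' converted to an annual hazard), fixed shares splitting total CVD risk
#' into myocardial infarction / angina / cardiac arrest / stroke, flat case
#' fatalities, a Gompertz-style background (non-CVD) mortality schedule, a
#' logistic diabetes-incidence baseline in age/sex/BMI, and a postacute
#' hazard multiplier for persons with established CVD.
#'
#' The sodium effect is routed either through systolic blood pressure
#' (`sodium$pathway = "bp"`, default: closing the sodium gap lowers SBP by
#' `bp_slope` mmHg per 1,000 mg/day, and treated persons whom the sodium
#' change moves from at-or-above to below the `treat_threshold`
#' hypertension cutoff stop antihypertensive treatment) or as a direct
#' relative risk (`"rr"`).
#'
#' `fixed_event_probs` is a calibration/testing hook: a named vector of
#' annual event probabilities (e.g. `c(mi = 0.1)`) that replaces the risk
#' function for all persons; unnamed events get probability 0.
#'
#' @param ... Named overrides of any default listed above.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    horizon = 5,
    discount_rate = 0.03,
    half_cycle = TRUE,
    growth_rate = 0.01,
    entrant_frac = 0.015,
    event_shares = c(mi = 0.30, angina = 0.25, cardiac_arrest = 0.05,
                     stroke = 0.40),
    case_fatality = c(mi = 0.25, angina = 0, stroke = 0.20,
                      cardiac_arrest = 0.90),
    postacute_multiplier = 2.0,
    rr_cap = 10,
    cap_quantile = 0.99,
    drift = c(sbp = 0.5, total_chol = 0.5, hdl = 0.0),
    mortality = c(rate35 = 5e-4, slope = 0.095),
    diabetes_inc = c(intercept = qlogis(0.006), age = 0.025, bmi = 0.08,
                     male = 0.10),
    sodium = list(pathway = "bp", bp_slope = 1.0, treat_threshold = 140),
    spec35 = NULL, # population_spec_age35() unless overridden
    fixed_event_probs = NULL,
    frs = default_frs_coefficients()
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("sim_config: unknown parameter(s): ",
                 paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(cfg, override)
  if (cfg$horizon < 1) abort("sim_config: horizon must be >= 1")
  if (cfg$discount_rate < 0) abort("sim_config: negative discount_rate")
  if (any(cfg$case_fatality < 0 | cfg$case_fatality > 1)) {
    abort("sim_config: case_fatality outside [0, 1]")
  }
  if (abs(sum(cfg$event_shares) - 1) > 1e-9) {
    abort("sim_config: event_shares must sum to 1")
  }
  structure(cfg, class = "sim_config")
}

#' Framingham general-CVD risk coefficients
#'
#' Sex-specific coefficients of the published general cardiovascular risk
#' function (log-transformed age, total and HDL cholesterol, systolic blood
#' pressure with separate treated/untreated terms, smoking, diabetes;
#' 10-year baseline survival and mean linear predictor). Used as the
#' default baseline annual CVD risk, fully replaceable in [sim_config()].
#'
#' @return A list with elements `male` and `female`.
#' @export
default_frs_coefficients <- function() {
  list(
    male = list(ln_age = 3.06117, ln_tc = 1.12370, ln_hdl = -0.93263,
                ln_sbp_untreated = 1.93303, ln_sbp_treated = 1.99881,
                smoker = 0.65451, diabetes = 0.57367,
                s0 = 0.88936, mean_lp = 23.9802),
    female = list(ln_age = 2.32888, ln_tc = 1.20904, ln_hdl = -0.70833,
                  ln_sbp_untreated = 2.76157, ln_sbp_treated = 2.82263,
                  smoker = 0.52873, diabetes = 0.69154,
                  s0 = 0.95012, mean_lp = 26.1931)
  )
}

# annual total-CVD hazard from the survival-form risk function
frs_annual_hazard <- function(table, frs) {
  male <- table$sex == "male"
  lp <- numeric(nrow(table))
  for (s in c("male", "female")) {
    k <- frs[[s]]
    i <- if (s == "male") male else !male
    if (!any(i)) next
    sbp_coef <- ifelse(table$htn_treated[i], k$ln_sbp_treated,
                       k$ln_sbp_untreated)
    lp[i] <- k$ln_age * log(pmax(30, table$age[i])) +
      k$ln_tc * log(table$total_chol[i]) +
      k$ln_hdl * log(table$hdl[i]) +
      sbp_coef * log(table$sbp[i]) +
      k$smoker * table$smoker[i] +
      k$diabetes * table$diabetes[i] - k$mean_lp
  }
  s0 <- ifelse(male, frs$male$s0, frs$female$s0)
  p10 <- pmin(0.95, 1 - s0^exp(lp))
  -log(1 - p10) / 10
}

#' Seed CVD health states from disease history
#'
#' Maps history flags to initial states: myocardial infarction and stroke
#' history jointly give the combined post-event state, either alone gives
#' its post-event state, angina alone gives the angina state, otherwise
#' well. Diabetes status is copied.
#'
#' @param table A person table with `history_mi`, `history_stroke`,
#'   `history_angina`, and `diabetes` columns.
#' @return A tibble: `person_id`, `state`, `diabetes`,
#'   `years_since_event` (0 for persons seeded into an event state,
#'   `NA` otherwise).
#' @export
seed_states <- function(table) {
  state <- rep("well", nrow(table))
  state[table$history_angina] <- "angina"
  state[table$history_stroke] <- "post_stroke"
  state[table$history_mi] <- "post_mi"
  state[table$history_mi & table$history_stroke] <- "post_mi_and_stroke"
  tibble(
    person_id = table$person_id,
    state = factor(state, levels = CVD_STATES),
    diabetes = table$diabetes,
    years_since_event = ifelse(state == "well", NA_integer_, 0L)
  )
}

#' One year of risk-factor drift
#'
#' Ages every person by one year and applies the configured linear drifts
#' to systolic blood pressure, total and HDL cholesterol. Deterministic.
#'
#' @param table A person table.
#' @param drift Named vector of per-year slopes (`sbp`, `total_chol`,
#'   `hdl`).
#' @return The drifted person table.
#' @export
update_risk_factors <- function(table, drift = sim_config()$drift) {
  table$age <- table$age + 1
  for (v in intersect(names(drift), names(table))) {
    table[[v]] <- table[[v]] + drift[[v]]
  }
  table
}

#' Annual event probabilities for each person
#'
#' Baseline annual CVD risk from the configured risk function is split into
#' myocardial infarction, angina, cardiac arrest, and stroke hazards by the
#' configured shares; each hazard is multiplied by the matching diet
#' relative risk (CHD RR scales MI/angina/cardiac arrest, stroke RR scales
#' stroke) and, for persons in post-event states, by the postacute
#' multiplier. Diabetes onset and background (non-CVD) death hazards are
#' added, and all competing hazards are resolved into one multinomial
#' probability row per person: `P(event i) = h_i / H * (1 - exp(-H))`, which
#' keeps every probability in `[0, 1]` and the row sum at most 1 regardless
#' of relative-risk scaling.
#'
#' @param table Person table rows (alive persons) with current risk factors.
#' @param states Matching state tibble from [seed_states()]/[step_year()].
#' @param diet_rr List of per-person relative-risk vectors: `chd`,
#'   `stroke`, `diabetes` (use 1 for no effect).
#' @param config A [sim_config()].
#' @return A tibble of per-person probabilities: `p_mi`, `p_angina`,
#'   `p_stroke`, `p_cardiac_arrest`, `p_diabetes_onset`, `p_other_death`.
#' @export
annual_event_probs <- function(table, states, diet_rr, config = sim_config()) {
  n <- nrow(table)
  stopifnot(nrow(states) == n)
  rr_chd <- rep_len(diet_rr$chd %||% 1, n)
  rr_stroke <- rep_len(diet_rr$stroke %||% 1, n)
  rr_dm <- rep_len(diet_rr$diabetes %||% 1, n)
  if (any(rr_chd < 0) || any(rr_stroke < 0) || any(rr_dm < 0)) {
    abort("annual_event_probs: negative relative risk")
  }

  if (!is.null(config$fixed_event_probs)) {
    fx <- config$fixed_event_probs
    h <- function(nm, rr) {
      p <- if (nm %in% names(fx)) fx[[nm]] else 0
      rep(-log(1 - min(p, 1 - 1e-12)), n) * rr
    }
    h_mi <- h("mi", rr_chd); h_ang <- h("angina", rr_chd)
    h_ca <- h("cardiac_arrest", rr_chd); h_st <- h("stroke", rr_stroke)
    h_dm <- h("diabetes_onset", rr_dm) * !states$diabetes
    h_od <- h("other_death", 1)
  } else {
    h_cvd <- frs_annual_hazard(table, config$frs)
    post <- states$state %in% c("angina", "post_mi", "post_stroke",
                                "post_mi_and_stroke")
    post_mult <- ifelse(post, config$postacute_multiplier, 1)
    sh <- config$event_shares
    h_mi <- h_cvd * sh[["mi"]] * rr_chd * post_mult
    h_ang <- h_cvd * sh[["angina"]] * rr_chd * post_mult
    h_ca <- h_cvd * sh[["cardiac_arrest"]] * rr_chd * post_mult
    h_st <- h_cvd * sh[["stroke"]] * rr_stroke * post_mult
    dmc <- config$diabetes_inc
    p_dm_base <- plogis(dmc[["intercept"]] + dmc[["age"]] * (table$age - 50) +
                          dmc[["bmi"]] * (table$bmi - 29) +
                          dmc[["male"]] * (table$sex == "male"))
    h_dm <- -log(1 - p_dm_base) * rr_dm * !states$diabetes
    mt <- config$mortality
    q_other <- pmin(0.9, mt[["rate35"]] * exp(mt[["slope"]] * (table$age - 35)))
    h_od <- rep_len(-log(1 - q_other), n)
  }

  H <- h_mi + h_ang + h_ca + h_st + h_dm + h_od
  scale <- ifelse(H > 0, (1 - exp(-H)) / H, 1)
  tibble(
    p_mi = h_mi * scale,
    p_angina = h_ang * scale,
    p_stroke = h_st * scale,
    p_cardiac_arrest = h_ca * scale,
    p_diabetes_onset = h_dm * scale,
    p_other_death = h_od * scale
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Advance all persons one simulation year
#'
#' Resolves, for each alive person, the competing events of one cycle from
#' the probability rows and two uniform draws per person (event selection
#' and case-fatality), applies state transitions, and returns the event
#' ledger rows. Dead persons are untouched (their draws are consumed but
#' ignored, preserving common-random-number alignment across scenarios).
#'
#' Transitions: MI (and survived cardiac arrest) move well/angina to
#' post-MI and post-stroke to the combined state; stroke moves well/angina
#' to post-stroke and post-MI to the combined state; angina only moves
#' well to angina; diabetes onset sets the diabetes flag. Fatal MI, stroke,
#' and cardiac arrest (per case-fatality) and background deaths are
#' absorbing.
#'
#' @param states State tibble (one row per person).
#' @param probs Probability tibble from [annual_event_probs()] (rows for
#'   alive persons, aligned with `alive` order).
#' @param u_event,u_fatal Uniform(0,1) vectors, one per person (all
#'   persons, alive or dead).
#' @param cycle_year Integer cycle index (for ledger rows).
#' @param case_fatality Named vector of case-fatality probabilities.
#' @return A list: `states` (updated tibble), `events` (ledger tibble with
#'   `person_id`, `cycle_year`, `event_type`, `fatal`).
#' @export
step_year <- function(states, probs, u_event, u_fatal, cycle_year = 1,
                      case_fatality = sim_config()$case_fatality) {
  n <- nrow(states)
  alive <- !(states$state %in% c("dead_cvd", "dead_other"))
  stopifnot(length(u_event) == n, length(u_fatal) == n,
            nrow(probs) == sum(alive))

  event <- rep(NA_character_, n)
  p <- as.matrix(probs[, c("p_mi", "p_angina", "p_stroke",
                           "p_cardiac_arrest", "p_diabetes_onset",
                           "p_other_death")])
  if (any(p < 0) || any(rowSums(p) > 1 + 1e-9)) {
    abort("step_year: invalid probability rows")
  }
  cum <- p
  for (j in 2:ncol(cum)) cum[, j] <- cum[, j - 1] + p[, j]
  # single multinomial draw per alive person: first category whose
  # cumulative probability exceeds the uniform, else no event
  u <- u_event[alive]
  pick <- rowSums(u > cum) + 1L
  labels <- c("mi", "angina", "stroke", "cardiac_arrest", "diabetes_onset",
              "other_death", "none")
  event[alive] <- labels[pick]

  fatal <- rep(FALSE, n)
  for (ev in c("mi", "stroke", "cardiac_arrest")) {
    idx <- which(event == ev)
    fatal[idx] <- u_fatal[idx] < case_fatality[[ev]]
  }

  st <- as.character(states$state)
  new_st <- st

  promote_mi <- which(event %in% c("mi", "cardiac_arrest") & !fatal)
  new_st[promote_mi] <- ifelse(
    st[promote_mi] %in% c("post_stroke", "post_mi_and_stroke"),
    "post_mi_and_stroke", "post_mi")
  promote_stroke <- which(event == "stroke" & !fatal)
  new_st[promote_stroke] <- ifelse(
    st[promote_stroke] %in% c("post_mi", "post_mi_and_stroke"),
    "post_mi_and_stroke", "post_stroke")
  promote_angina <- which(event == "angina" & st == "well")
  new_st[promote_angina] <- "angina"
  new_st[which(event %in% c("mi", "stroke", "cardiac_arrest") & fatal)] <-
    "dead_cvd"
  new_st[which(event == "other_death")] <- "dead_other"

  dm_onset <- which(event == "diabetes_onset")
  diabetes <- states$diabetes
  diabetes[dm_onset] <- TRUE

  had_event <- !is.na(event) & event %in%
    c("mi", "angina", "stroke", "cardiac_arrest")
  yse <- states$years_since_event
  yse[alive] <- yse[alive] + 1L
  yse[had_event] <- 0L

  ledger_idx <- which(!is.na(event) & event != "none")
  ev_out <- event[ledger_idx]
  events <- tibble(
    person_id = states$person_id[ledger_idx],
    cycle_year = cycle_year,
    event_type = ev_out,
    fatal = fatal[ledger_idx] | ev_out == "other_death"
  )
  # fatal CVD events are additionally logged as a cvd_death row
  cvd_fatal <- which(fatal & event %in% c("mi", "stroke", "cardiac_arrest"))
  if (length(cvd_fatal) > 0) {
    events <- bind_rows(events, tibble(
      person_id = states$person_id[cvd_fatal],
      cycle_year = cycle_year, event_type = "cvd_death", fatal = TRUE
    ))
  }

  states$state <- factor(new_st, levels = CVD_STATES)
  states$diabetes <- diabetes
  states$years_since_event <- yse
  list(states = states, events = events)
}

# per-person summed log relative risk at attenuation 1; the age-band
# multiplier is a single per-person factor applied at run time
base_log_rr <- function(table, factors, disease) {
  out <- numeric(nrow(table))
  for (i in seq_len(nrow(factors))) {
    f <- factors[i, ]
    col <- paste0("intake_", f$factor)
    if (!col %in% names(table)) {
      abort(paste0("run_microsim: missing intake column '", col, "'"))
    }
    rr_unit <- f[[paste0("rr_", disease)]]
    if (rr_unit == 1) next
    out <- out + log(rr_unit) * intake_gap(table[[col]], f) / f$unit_size
  }
  out
}

#' Run the microsimulation under a diet scenario
#'
#' Simulates the cohort for `config$horizon` yearly cycles under the given
#' scenario: intakes are truncated at the configured quantile, the scenario
#' transform applied, per-person diet relative risks computed (log-linear,
#' age-attenuated), and each cycle resolves competing events, applies state
#' transitions and risk-factor drift, and adds an entrant cohort of
#' 35-year-olds (sized `round(n * entrant_frac)` growing at `growth_rate`).
#' First and last cycles carry half-cycle person-time weights when
#' `half_cycle` is on.
#'
#' All randomness derives from `seed` and the cycle index, never from the
#' scenario, so two runs on the same population with different scenarios
#' use common random numbers: persons experience identical event draws
#' wherever their event probabilities coincide.
#'
#' Under the blood-pressure sodium pathway, the counterfactual reduction of
#' sodium intake lowers systolic blood pressure by `bp_slope` mmHg per
#' 1,000 mg/day of gap closed, and treated persons whose adjusted SBP falls
#' below `treat_threshold` stop antihypertensive treatment; sodium then
#' contributes no direct relative risk.
#'
#' @param table Person table ([generate_population()]).
#' @param scn A [scenario()] (default observed diet).
#' @param factors Diet-factor table ([default_diet_factors()]).
#' @param config A [sim_config()].
#' @param seed Master seed for the run.
#' @return An object of class `"cmd_sim"`: list with `events` (ledger
#'   tibble), `panel` (person-year tibble: `person_id`, `cycle_year`,
#'   `state`, `diabetes`, `htn_treated`, `age`, `weight`), `population`
#'   (base + entrant attributes), `scenario`, `config`, `seed`.
#' @export
run_microsim <- function(table, scn = scenario_observed(),
                         factors = default_diet_factors(),
                         config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (config$horizon < 1) abort("run_microsim: horizon must be >= 1")

  n0 <- nrow(table)
  spec35 <- config$spec35 %||% population_spec_age35()
  entrant_base <- as.integer(round(n0 * config$entrant_frac))

  prepare <- function(tbl) {
    tbl <- cap_intakes(tbl, factors, config$cap_quantile)
    obs_sodium <- if ("intake_sodium" %in% names(tbl)) {
      tbl$intake_sodium
    }
    eff <- apply_scenario(tbl, scn, factors)
    fac <- factors
    if (identical(config$sodium$pathway, "bp") &&
        "intake_sodium" %in% names(tbl)) {
      delta <- pmax(0, obs_sodium - eff$intake_sodium)
      sbp_drop <- config$sodium$bp_slope * delta / 1000
      sbp_before <- eff$sbp
      eff$sbp <- eff$sbp - sbp_drop
      # treatment stops only when the sodium change moves a treated person
      # below the hypertension threshold they were at or above before
      stop_tx <- eff$htn_treated & sbp_drop > 0 &
        sbp_before >= config$sodium$treat_threshold &
        eff$sbp < config$sodium$treat_threshold
      eff$htn_treated <- eff$htn_treated & !stop_tx
      fac$rr_chd[fac$factor == "sodium"] <- 1
      fac$rr_stroke[fac$factor == "sodium"] <- 1
      fac$rr_diabetes[fac$factor == "sodium"] <- 1
    }
    eff$lrr_chd <- base_log_rr(eff, fac, "chd")
    eff$lrr_stroke <- base_log_rr(eff, fac, "stroke")
    eff$lrr_diabetes <- base_log_rr(eff, fac, "diabetes")
    eff
  }

  cur <- prepare(table)
  states <- seed_states(cur)
  H <- config$horizon
  panel_list <- vector("list", H)
  event_list <- vector("list", H)

  for (t in seq_len(H)) {
    if (t > 1) {
      cur <- update_risk_factors(cur, config$drift)
      if (entrant_base > 0) {
        ent <- make_entrant_cohort(spec35, entrant_base, year = t - 2,
                                   growth = config$growth_rate, seed = seed)
        if (nrow(ent) > 0) {
          ent$person_id <- max(cur$person_id) + seq_len(nrow(ent))
          ent <- prepare(ent)
          cur <- bind_rows(cur, ent)
          states <- bind_rows(states, seed_states(ent))
        }
      }
    }
    alive <- !(states$state %in% c("dead_cvd", "dead_other"))
    w <- if (config$half_cycle && (t == 1 || t == H)) 0.5 else 1
    panel_list[[t]] <- tibble(
      person_id = cur$person_id[alive],
      cycle_year = t,
      state = states$state[alive],
      diabetes = states$diabetes[alive],
      htn_treated = cur$htn_treated[alive],
      age = cur$age[alive],
      weight = w
    )
    att <- age_attenuation(cur$age[alive])
    diet_rr <- list(
      chd = pmin(config$rr_cap, exp(att * cur$lrr_chd[alive])),
      stroke = pmin(config$rr_cap, exp(att * cur$lrr_stroke[alive])),
      diabetes = pmin(config$rr_cap, exp(att * cur$lrr_diabetes[alive]))
    )
    probs <- annual_event_probs(cur[alive, , drop = FALSE],
                                states[alive, , drop = FALSE],
                                diet_rr, config)
    draws <- with_seed(derive_seed(seed, "cycle", t), {
      list(u_event = runif(nrow(cur)), u_fatal = runif(nrow(cur)))
    })
    stepped <- step_year(states, probs, draws$u_event, draws$u_fatal,
                         cycle_year = t,
                         case_fatality = config$case_fatality)
    states <- stepped$states
    event_list[[t]] <- stepped$events
    # mirror onset into the person table so the risk function sees it
    cur$diabetes <- states$diabetes
  }

  structure(
    list(
      events = bind_rows(event_list),
      panel = bind_rows(panel_list),
      population = cur,
      scenario = scn$name,
      config = config,
      seed = seed,
      n_base = n0
    ),
    class = "cmd_sim"
  )
}

#' @export
print.cmd_sim <- function(x, ...) {
  cat("<cmd_sim> scenario:", x$scenario,
      "| persons:", nrow(x$population),
      "| cycles:", x$config$horizon,
      "| events:", nrow(x$events), "\n")
  invisible(x)
}
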
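# Cost accounting: events and person-year states are converted into
# discounted, inflation-adjusted costs split into acute, chronic CVD,
# chronic diabetes, and drug components, then annualized per capita from
# the final cross-sectional cycle.

#' Cost parameters
#'
#' Acute per-event costs, annual chronic disease-management costs by CVD
#' state and for diabetes, annual drug costs per treated person-year, the
#' discount rate, and an inflation table to 2018 USD. The bundled dollar
#' values are **synthetic placeholders** of realistic magnitude (the
#' original model's validated cost inputs are not bundled); supply your own
#' for substantive estimates.
#'
#' @param acute Named vector of per-event 2018-USD costs (`mi`, `angina`,
#'   `stroke`, `cardiac_arrest`). Fatal events still incur their acute cost.
#' @param chronic_cvd Named vector of USD per person-year by CVD state
#'   (`angina`, `post_mi`, `post_stroke`, `post_mi_and_stroke`).
#' @param chronic_diabetes USD per diabetic person-year.
#' @param drug Named vector of USD per treated person-year
#'   (`antihypertensive`).
#' @param discount_rate Annual discount fraction (default 0.03).
#' @param base_year Year the cost inputs are expressed in.
#' @param inflation Tibble `year`, `multiplier` converting `year`-USD to
#'   2018 USD (`multiplier = 1` at 2018).
#' @return A list of class `"cost_parameters"`.
#' @export
cost_parameters <- function(acute = c(mi = 23000, angina = 9000,
                                      stroke = 22000, cardiac_arrest = 26000),
                            chronic_cvd = c(angina = 2200, post_mi = 2800,
                                            post_stroke = 4000,
                                            post_mi_and_stroke = 5800),
                            chronic_diabetes = 2100,
                            drug = c(antihypertensive = 350),
                            discount_rate = 0.03,
                            base_year = 2018,
                            inflation = NULL) {
  if (is.null(inflation)) {
    inflation <- tibble(
      year = 2013:2018,
      multiplier = c(1.089, 1.071, 1.060, 1.047, 1.025, 1.000)
    )
  }
  if (any(acute < 0) || any(chronic_cvd < 0) || chronic_diabetes < 0 ||
      any(drug < 0)) {
    abort("cost_parameters: costs must be >= 0")
  }
  if (discount_rate < 0) abort("cost_parameters: negative discount_rate")
  structure(
    list(acute = acute, chronic_cvd = chronic_cvd,
         chronic_diabetes = chronic_diabetes, drug = drug,
         discount_rate = discount_rate, base_year = base_year,
         inflation = as_tibble(inflation)),
    class = "cost_parameters"
  )
}

#' Discount a cost to present value
#'
#' `amount / (1 + rate)^cycle_year`; year 0 is undiscounted.
#'
#' @param amount Nonnegative cost(s).
#' @param cycle_year Nonnegative year index (vectorized).
#' @param rate Annual discount fraction (default 3%).
#' @return Discounted amount(s).
#' @examples
#' discount(100, 1) # 97.0874
#' @export
discount <- function(amount, cycle_year, rate = 0.03) {
  if (rate < 0) abort("discount: negative rate")
  if (any(amount < 0)) abort("discount: negative amount")
  if (any(cycle_year < 0)) abort("discount: negative cycle_year")
  amount / (1 + rate)^cycle_year
}

#' Inflate a cost to 2018 USD
#'
#' @param amount Cost(s) in `from_year` dollars.
#' @param from_year Year the amount is expressed in.
#' @param inflation Tibble `year`, `multiplier` (multiplier to 2018 USD).
#' @return Amount(s) in 2018 USD.
#' @export
inflate <- function(amount, from_year, inflation = cost_parameters()$inflation) {
  i <- match(from_year, inflation$year)
  if (any(is.na(i))) {
    abort(paste0("inflate: year ", paste(from_year[is.na(i)], collapse = ", "),
                 " missing from inflation table"))
  }
  amount * inflation$multiplier[i]
}

#' Accumulate discounted costs from a simulation
#'
#' Books each event's acute cost in its cycle (fatal events included), each
#' person-year in a post-event CVD state at that state's chronic cost, each
#' diabetic person-year at the chronic diabetes cost, and each treated
#' person-year at the antihypertensive drug cost. Person-year costs carry
#' the panel's half-cycle person-time weights; acute event costs carry the
#' same cycle weight. Everything is discounted at `params$discount_rate`
#' with cycle 1 as year 1 (year 0 undiscounted) and inflated from
#' `params$base_year` to 2018 USD.
#'
#' Because the panel records each person's state at the start of the cycle,
#' chronic costs begin the cycle *after* the event (the postacute
#' definition).
#'
#' @param sim A `"cmd_sim"` from [run_microsim()].
#' @param params A [cost_parameters()].
#' @return An object of class `"cmd_costs"`: list with `person_year`
#'   (tibble: `person_id`, `cycle_year`, `acute`, `chronic_cvd`,
#'   `chronic_diabetes`, `drug`, `total`), `params`, and the simulation
#'   metadata needed for annualization.
#' @export
accumulate_costs <- function(sim, params = cost_parameters()) {
  stopifnot(inherits(sim, "cmd_sim"), inherits(params, "cost_parameters"))
  infl <- inflate(1, params$base_year, params$inflation)
  rate <- params$discount_rate
  panel <- sim$panel

  # person-year (chronic + drug) costs; panel rows are unique per
  # (person, cycle), so acute event costs can be matched onto them
  cvd_cost <- params$chronic_cvd[as.character(panel$state)]
  cvd_cost[is.na(cvd_cost)] <- 0
  dm_cost <- ifelse(panel$diabetes, params$chronic_diabetes, 0)
  drug_cost <- ifelse(panel$htn_treated, params$drug[["antihypertensive"]], 0)
  disc <- discount(1, panel$cycle_year, rate) * infl * panel$weight
  H <- sim$config$horizon
  key <- panel$person_id * (H + 1) + panel$cycle_year

  acute <- numeric(nrow(panel))
  ev <- sim$events |>
    filter(!.data$event_type %in% c("diabetes_onset", "cvd_death",
                                    "other_death"))
  if (nrow(ev) > 0) {
    missing <- setdiff(unique(ev$event_type), names(params$acute))
    if (length(missing) > 0) {
      abort(paste0("accumulate_costs: no acute cost for event type(s): ",
                   paste(missing, collapse = ", ")))
    }
    w_ev <- ifelse(sim$config$half_cycle &
                     (ev$cycle_year == 1 | ev$cycle_year == H), 0.5, 1)
    ev_amt <- as.numeric(params$acute[ev$event_type]) *
      discount(1, ev$cycle_year, rate) * infl * w_ev
    ev_key <- ev$person_id * (H + 1) + ev$cycle_year
    agg <- rowsum(ev_amt, group = ev_key)
    acute[match(as.numeric(rownames(agg)), key)] <- agg[, 1]
  }

  person_year <- tibble(
    person_id = panel$person_id,
    cycle_year = panel$cycle_year,
    acute = acute,
    chronic_cvd = as.numeric(cvd_cost) * disc,
    chronic_diabetes = dm_cost * disc,
    drug = drug_cost * disc
  ) |>
    mutate(total = .data$acute + .data$chronic_cvd +
             .data$chronic_diabetes + .data$drug)

  structure(
    list(person_year = person_year, params = params,
         scenario = sim$scenario, horizon = sim$config$horizon,
         half_cycle = sim$config$half_cycle, seed = sim$seed),
    class = "cmd_costs"
  )
}

#' Annualized per-capita costs from the final cross-sectional cycle
#'
#' The simulation's final cycle is the cross-section used for 1-year
#' results: each category's final-cycle cost total is divided by the
#' final-cycle person-time (so half-cycle weights cancel), giving an
#' annualized per-capita cost rate. Components sum exactly to the total.
#'
#' @param costs A `"cmd_costs"` from [accumulate_costs()].
#' @param sim The matching `"cmd_sim"`.
#' @param by Optional character vector of person attributes from the
#'   population table (e.g. `"sex"`, `"insurance"`) to group by.
#' @return A tibble with one row (or one per group): `acute`,
#'   `chronic_cvd`, `chronic_diabetes`, `drug`, `total`, `n_alive`,
#'   `person_time`.
#' @export
annualize_costs <- function(costs, sim, by = NULL) {
  stopifnot(inherits(costs, "cmd_costs"), inherits(sim, "cmd_sim"))
  H <- costs$horizon
  final_panel <- sim$panel |> filter(.data$cycle_year == H)
  if (nrow(final_panel) == 0) {
    abort("annualize_costs: no persons alive in the final cycle")
  }
  final_costs <- costs$person_year |> filter(.data$cycle_year == H)

  join_attrs <- function(df) {
    if (is.null(by)) return(mutate(df, .grp = "all"))
    cols <- setdiff(by, names(df))
    if (length(cols) > 0) {
      attrs <- sim$population[, c("person_id", cols), drop = FALSE]
      df <- left_join(df, attrs, by = "person_id")
    }
    tidyr::unite(df, ".grp", dplyr::all_of(by), sep = "/", remove = FALSE)
  }
  fp <- join_attrs(final_panel)
  fc <- join_attrs(final_costs)

  pt <- fp |> group_by(.data$.grp) |>
    summarise(n_alive = dplyr::n(), person_time = sum(.data$weight),
              .groups = "drop")
  cs <- fc |> group_by(.data$.grp) |>
    summarise(across(c("acute", "chronic_cvd", "chronic_diabetes", "drug"),
                     sum), .groups = "drop")
  out <- left_join(pt, cs, by = ".grp") |>
    mutate(across(c("acute", "chronic_cvd", "chronic_diabetes", "drug"),
                  ~ tidyr::replace_na(.x, 0) / .data$person_time)) |>
    mutate(total = .data$acute + .data$chronic_cvd +
             .data$chronic_diabetes + .data$drug)
  if (is.null(by)) {
    out |> select(-".grp") |>
      select("acute", "chronic_cvd", "chronic_diabetes", "drug", "total",
             "n_alive", "person_time")
  } else {
    grp_attrs <- fp |> distinct(.data$.grp, dplyr::pick(dplyr::all_of(by)))
    out |> left_join(grp_attrs, by = ".grp") |> select(-".grp") |>
      select(dplyr::all_of(by), "acute", "chronic_cvd", "chronic_diabetes",
             "drug", "total", "n_alive", "person_time")
  }
}
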
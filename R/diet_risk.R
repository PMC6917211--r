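# Dietary-factor definitions and the dose-response machinery: intake gaps
# relative to optimal levels, log-linear per-unit relative risks with
# age-band attenuation, multiplicative combination across factors, and
# scenario transforms (observed vs. optimal counterfactuals).

#' Default dietary-factor definitions
#'
#' The ten dietary factors with their units, directions, and optimal intake
#' levels (fruits excluding juices 300 g/day; vegetables including legumes
#' 400 g/day; nuts/seeds 20.2 g/day; whole grains 125 g/day; unprocessed red
#' meat 14.3 g/day; processed meat and sugar-sweetened beverages: no intake;
#' PUFA 11% of energy; seafood omega-3 250 mg/day; sodium 2,000 mg/day).
#'
#' The per-unit relative risks (`rr_chd`, `rr_stroke`, `rr_diabetes`) are
#' **synthetic defaults**: plausible magnitudes in the style of published
#' diet-disease meta-analyses, oriented so each value is the risk at one
#' `unit_size` of intake gap relative to optimal (hence `>= 1`; `1` means no
#' modeled causal link to that disease). The original model's calibrated
#' effect sizes are not bundled; supply your own via this table or
#' [load_config()] for substantive estimates. `se_*` columns are standard
#' errors of the log relative risks used for uncertainty draws.
#'
#' @return A tibble with one row per factor: `factor`, `unit`, `direction`
#'   (`"protective"`/`"harmful"`), `optimal`, `unit_size` (gap per one RR
#'   unit, in the factor's unit), `rr_chd`, `rr_stroke`, `rr_diabetes`,
#'   `se_chd`, `se_stroke`, `se_diabetes`.
#' @export
default_diet_factors <- function() {
  tibble(
    factor = c("fruits", "vegetables", "nuts_seeds", "whole_grains",
               "red_meat", "processed_meat", "ssb", "pufa",
               "seafood_omega3", "sodium"),
    unit = c("g/day", "g/day", "g/day", "g/day", "g/day", "g/day",
             "servings/day", "%energy", "mg/day", "mg/day"),
    direction = c("protective", "protective", "protective", "protective",
                  "harmful", "harmful", "harmful", "protective",
                  "protective", "harmful"),
    optimal  = c(300, 400, 20.2, 125, 14.3, 0, 0, 11, 250, 2000),
    unit_size = c(100, 100, 20.2, 50, 100, 50, 1, 5, 100, 1000),
    rr_chd      = c(1.07, 1.06, 1.33, 1.05, 1.00, 1.27, 1.12, 1.11, 1.09, 1.12),
    rr_stroke   = c(1.14, 1.09, 1.00, 1.00, 1.00, 1.00, 1.07, 1.00, 1.00, 1.19),
    rr_diabetes = c(1.00, 1.00, 1.04, 1.13, 1.17, 1.44, 1.18, 1.00, 1.00, 1.00),
    se_chd      = c(0.02, 0.02, 0.05, 0.02, 0.00, 0.04, 0.03, 0.03, 0.03, 0.03),
    se_stroke   = c(0.03, 0.03, 0.00, 0.00, 0.00, 0.00, 0.03, 0.00, 0.00, 0.04),
    se_diabetes = c(0.00, 0.00, 0.03, 0.03, 0.04, 0.06, 0.03, 0.00, 0.00, 0.00)
  )
}

#' Default age-band attenuation of log relative risks
#'
#' Diet-disease log relative risks attenuate with age; the schedule is
#' piecewise-constant over age bands, 1.0 at 35-44 declining to a floor of
#' 0.4 at 75+.
#'
#' @return Tibble with columns `lo`, `hi`, `mult` (multiplier on log-RR,
#'   in `[0, 1]`).
#' @export
default_age_bands <- function() {
  tibble(
    lo = c(35, 45, 55, 65, 75),
    hi = c(44, 54, 64, 74, Inf),
    mult = c(1.00, 0.85, 0.70, 0.55, 0.40)
  )
}

# vectorized band lookup; ages below the first band get the first multiplier
age_attenuation <- function(age, bands = default_age_bands()) {
  idx <- findInterval(age, bands$lo)
  idx[idx < 1] <- 1L
  bands$mult[idx]
}

#' Intake gap relative to the optimal level
#'
#' Distance from optimal in the harmful direction: for protective factors
#' `max(0, optimal - intake)`, for harmful factors `max(0, intake -
#' optimal)`. Persons at or better than optimal have gap 0 — no extra
#' benefit beyond optimal is modeled.
#'
#' @param intake Nonnegative intake(s) in the factor's unit.
#' @param factor One row of a diet-factor table.
#' @return Nonnegative gap(s), same length as `intake`.
#' @examples
#' f <- dplyr::filter(default_diet_factors(), factor == "nuts_seeds")
#' intake_gap(12.5, f) # 7.7 g/day below the 20.2 g/day optimum
#' @export
intake_gap <- function(intake, factor) {
  if (any(intake < 0)) abort("intake_gap: negative intake")
  if (factor$direction == "protective") {
    pmax(0, factor$optimal - intake)
  } else {
    pmax(0, intake - factor$optimal)
  }
}

#' Relative risk for an intake gap
#'
#' Log-linear dose-response: `RR = exp(a(age) * log(rr_unit) * gap /
#' unit_size)` where `rr_unit` is the per-unit relative risk for the disease
#' and `a(age)` the age-band attenuation multiplier. Always `>= 1`, equal to
#' 1 at gap 0, and capped at `rr_cap`. A factor with no configured link to
#' the disease (`rr_unit = 1`) returns 1.
#'
#' @param gap Nonnegative intake gap(s), from [intake_gap()].
#' @param factor One row of a diet-factor table.
#' @param disease One of `"chd"`, `"stroke"`, `"diabetes"`.
#' @param age Age(s) in years (scalar or same length as `gap`).
#' @param age_bands Attenuation schedule ([default_age_bands()]).
#' @param rr_cap Ceiling on the returned relative risk.
#' @return Relative risk(s) in `[1, rr_cap]`.
#' @examples
#' f <- dplyr::filter(default_diet_factors(), factor == "ssb")
#' relative_risk(2, f, "diabetes", age = 40)
#' @export
relative_risk <- function(gap, factor, disease, age = 40,
                          age_bands = default_age_bands(), rr_cap = 10) {
  if (any(gap < 0)) abort("relative_risk: negative gap")
  col <- paste0("rr_", disease)
  if (!col %in% names(factor)) return(rep(1, length(gap)))
  rr_unit <- factor[[col]]
  if (!is.finite(rr_unit) || rr_unit <= 0) {
    abort(paste0("relative_risk: malformed rr for '", factor$factor, "'"))
  }
  a <- age_attenuation(age, age_bands)
  pmin(rr_cap, exp(a * log(rr_unit) * gap / factor$unit_size))
}

# 99th-percentile truncation of intakes before gap computation, bounding
# extreme relative risks from long-tailed intake draws
cap_intakes <- function(table, factors, cap_quantile = 0.99) {
  if (is.null(cap_quantile) || nrow(table) == 0) return(table)
  for (f in factors$factor) {
    col <- paste0("intake_", f)
    if (col %in% names(table)) {
      cap <- quantile(table[[col]], cap_quantile, names = FALSE, type = 7)
      table[[col]] <- pmin(table[[col]], cap)
    }
  }
  table
}

#' Combined relative risk across dietary factors
#'
#' Multiplicative combination: per-person product over the factors of each
#' factor's disease-specific relative risk at the person's (capped) intake.
#' Equals the single-factor RR when only one factor has a nonzero gap, and 1
#' when all intakes are optimal.
#'
#' @param table A person table with `intake_*` columns and `age`.
#' @param factors Diet-factor table ([default_diet_factors()]).
#' @param disease One of `"chd"`, `"stroke"`, `"diabetes"`.
#' @param age_bands,rr_cap Passed to [relative_risk()].
#' @param cap_quantile Intake truncation quantile (`NULL` to disable).
#' @return Numeric vector, one combined RR per person.
#' @export
combined_rr <- function(table, factors, disease,
                        age_bands = default_age_bands(), rr_cap = 10,
                        cap_quantile = 0.99) {
  if (nrow(factors) == 0) abort("combined_rr: no factors")
  table <- cap_intakes(table, factors, cap_quantile)
  rr <- rep(1, nrow(table))
  for (i in seq_len(nrow(factors))) {
    f <- factors[i, ]
    col <- paste0("intake_", f$factor)
    if (!col %in% names(table)) {
      abort(paste0("combined_rr: missing intake column '", col, "'"))
    }
    gap <- intake_gap(table[[col]], f)
    rr <- rr * relative_risk(gap, f, disease, table$age, age_bands, rr_cap)
  }
  pmin(rr, rr_cap)
}

#' Scenario constructors
#'
#' A scenario maps each dietary factor to an intake transform: `"observed"`
#' (identity), `"optimal"` (move persons worse than optimal to the optimal
#' level; better-than-optimal intakes are left unchanged), or a fixed value.
#' `scenario_observed()` is the all-identity baseline; `scenario_optimal()`
#' sets the named factors (default all) to optimal.
#'
#' @param name Scenario name.
#' @param transforms Named list mapping factor name to `"observed"`,
#'   `"optimal"`, or a single number (fixed intake).
#' @return A list of class `"cmd_scenario"`.
#' @export
scenario <- function(name, transforms) {
  structure(list(name = name, transforms = transforms),
            class = "cmd_scenario")
}

#' @rdname scenario
#' @param factors Character vector of factor names to set to optimal
#'   (`scenario_optimal`), or all factor names (`scenario_observed`).
#' @export
scenario_observed <- function(factors = default_diet_factors()$factor) {
  scenario("observed", setNames(as.list(rep("observed", length(factors))),
                                factors))
}

#' @rdname scenario
#' @export
scenario_optimal <- function(factors = default_diet_factors()$factor) {
  tr <- setNames(as.list(rep("observed", length(default_diet_factors()$factor))),
                 default_diet_factors()$factor)
  unknown <- setdiff(factors, names(tr))
  if (length(unknown) > 0) tr[unknown] <- "optimal" # allow custom factor sets
  tr[intersect(factors, names(tr))] <- "optimal"
  nm <- if (length(factors) == length(tr)) "optimal_all" else
    paste0("optimal_", paste(factors, collapse = "+"))
  scenario(nm, tr)
}

#' Apply a diet scenario to a person table
#'
#' Transforms the `intake_*` columns per the scenario. The `"optimal"`
#' transform only moves individuals *worse* than optimal to the optimal
#' level (protective: raise to optimal if below; harmful: lower to optimal
#' if above); it is idempotent. `"observed"` is the identity.
#'
#' @param table A person table.
#' @param scn A [scenario()].
#' @param factors Diet-factor table supplying optimal levels/directions.
#' @return The transformed person table.
#' @export
apply_scenario <- function(table, scn, factors = default_diet_factors()) {
  stopifnot(inherits(scn, "cmd_scenario"))
  for (nm in names(scn$transforms)) {
    tr <- scn$transforms[[nm]]
    if (identical(tr, "observed")) next
    col <- paste0("intake_", nm)
    frow <- factors[factors$factor == nm, ]
    if (nrow(frow) != 1 || !col %in% names(table)) {
      abort(paste0("apply_scenario: unknown factor '", nm, "'"))
    }
    if (identical(tr, "optimal")) {
      table[[col]] <- if (frow$direction == "protective") {
        pmax(table[[col]], frow$optimal)
      } else {
        pmin(table[[col]], frow$optimal)
      }
    } else if (is.numeric(tr) && length(tr) == 1) {
      table[[col]] <- rep(tr, nrow(table))
    } else {
      abort(paste0("apply_scenario: invalid transform for '", nm, "'"))
    }
  }
  table
}

#' Draw a relative-risk set from its uncertainty distribution
#'
#' Replaces each per-unit relative risk by a lognormal draw,
#' `exp(N(log rr, se^2))`, using the factor table's `se_*` columns. Factors
#' with `se = 0` keep their point estimates. Seed-deterministic; used to
#' propagate effect-size uncertainty into Monte-Carlo confidence intervals.
#'
#' @param factors Diet-factor table with `rr_*` and `se_*` columns.
#' @param seed Integer seed.
#' @return A diet-factor table with perturbed `rr_*` columns.
#' @export
draw_rr_set <- function(factors, seed = 1) {
  diseases <- c("chd", "stroke", "diabetes")
  se_cols <- paste0("se_", diseases)
  if (!all(se_cols %in% names(factors))) {
    abort("draw_rr_set: factor table lacks se_chd/se_stroke/se_diabetes")
  }
  with_seed(derive_seed(seed, "rr_draw"), {
    for (d in diseases) {
      rr <- factors[[paste0("rr_", d)]]
      se <- factors[[paste0("se_", d)]]
      factors[[paste0("rr_", d)]] <- exp(rnorm(length(rr), log(rr), se))
    }
  })
  factors
}
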
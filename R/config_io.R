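# Configuration round-tripping and the end-to-end pipeline driver:
# generate -> run -> attribute -> report, with a manifest recording seeds
# and file hashes so any run can be reproduced exactly.

CONFIG_SECTIONS <- c("run", "population", "factors", "sim", "costs",
                     "payer_mix")

#' Read and write person tables as CSV
#'
#' RFC 4180 CSV with a fixed header: `person_id`, demographics (`sex`,
#' `age`, `race`, `education`, `insurance`), clinical risk factors,
#' logical flags, `sample_weight`, and one `intake_<factor>` column per
#' dietary factor. `read_person_table()` restores the categorical columns
#' as factors with the package's canonical level order.
#'
#' @param table A person table.
#' @param path File path.
#' @return `write_person_table()` returns `path` invisibly;
#'   `read_person_table()` returns the person table as a tibble.
#' @export
write_person_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_person_table
#' @export
read_person_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("read_person_table: no such file: ", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  spec <- population_spec()
  for (v in c("sex", "race", "education", "insurance")) {
    if (v %in% names(df)) {
      df[[v]] <- factor(df[[v]], levels = names(spec[[v]]))
    }
  }
  as_tibble(df)
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration with sections `run` (`n`, `seed`,
#' `population_size`, `ci_draws`), `population` ([population_spec()]
#' marginal overrides; an intake correlation matrix is supplied through
#' the R API only), `factors` (diet-factor table rows), `sim`
#' ([sim_config()] overrides), `costs` ([cost_parameters()] overrides),
#' and `payer_mix`. Unknown sections or unknown keys within a section are
#' rejected with an error naming the key; missing values are filled with
#' the package defaults (discount rate 0.03, horizon 5, etc.).
#'
#' @param path Path to a YAML file.
#' @return A validated list of class `"cmd_config"` with elements `run`,
#'   `factors` (tibble), `sim` (`"sim_config"`), `costs`
#'   (`"cost_parameters"`), `payer_mix` (tibble), `population`
#'   (`"population_spec"`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("load_config: no such file: ", path))
  raw <- yaml::read_yaml(path)
  build_config(raw)
}

build_config <- function(raw = list()) {
  unknown <- setdiff(names(raw), CONFIG_SECTIONS)
  if (length(unknown) > 0) {
    abort(paste0("config: unknown section(s): ",
                 paste(unknown, collapse = ", "),
                 " (allowed: ", paste(CONFIG_SECTIONS, collapse = ", "), ")"))
  }
  run_defaults <- list(n = 20000, seed = 1, population_size = 167.4e6,
                       ci_draws = 200)
  run_raw <- raw$run %||% list()
  unknown <- setdiff(names(run_raw), names(run_defaults))
  if (length(unknown) > 0) {
    abort(paste0("config: unknown key(s) in 'run': ",
                 paste(unknown, collapse = ", ")))
  }
  run <- modifyList(run_defaults, run_raw)
  if (run$n < 0) abort("config: run.n must be >= 0")

  factors <- if (is.null(raw$factors)) {
    default_diet_factors()
  } else {
    fac <- bind_rows(lapply(raw$factors, as_tibble))
    need <- names(default_diet_factors())
    miss <- setdiff(need, names(fac))
    if (length(miss) > 0) {
      abort(paste0("config: factors missing column(s): ",
                   paste(miss, collapse = ", ")))
    }
    fac[, need]
  }
  sim <- do.call(sim_config, normalize_sim_overrides(raw$sim %||% list()))
  costs <- do.call(cost_parameters, normalize_cost_overrides(raw$costs %||% list()))
  payer_mix <- if (is.null(raw$payer_mix)) {
    default_payer_mix()
  } else {
    bind_rows(lapply(raw$payer_mix, as_tibble))
  }
  population <- do.call(
    population_spec,
    normalize_population_overrides(raw$population %||% list()))
  structure(
    list(run = run, factors = factors, sim = sim, costs = costs,
         payer_mix = payer_mix, population = population),
    class = "cmd_config"
  )
}

# yaml collapses named vectors to lists; restore the shapes sim_config()
# and cost_parameters() expect
normalize_sim_overrides <- function(x) {
  vec_keys <- c("event_shares", "case_fatality", "drift", "mortality",
                "diabetes_inc")
  for (k in intersect(vec_keys, names(x))) x[[k]] <- unlist(x[[k]])
  if ("frs" %in% names(x)) x$frs <- lapply(x$frs, as.list)
  x
}

normalize_population_overrides <- function(x) {
  allowed <- c("age_bands", "sex", "race", "education", "insurance",
               "continuous", "prevalence", "intakes", "weight_shape")
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0) {
    abort(paste0("config: unknown key(s) in 'population': ",
                 paste(unknown, collapse = ", ")))
  }
  tab_keys <- c("age_bands", "continuous", "intakes")
  for (k in intersect(tab_keys, names(x))) {
    x[[k]] <- bind_rows(lapply(x[[k]], as_tibble))
  }
  for (k in intersect(c("sex", "race", "education", "insurance",
                        "prevalence"), names(x))) {
    x[[k]] <- unlist(x[[k]])
  }
  x
}

normalize_cost_overrides <- function(x) {
  for (k in intersect(c("acute", "chronic_cvd", "drug"), names(x))) {
    x[[k]] <- unlist(x[[k]])
  }
  if ("inflation" %in% names(x)) x$inflation <- bind_rows(lapply(x$inflation, as_tibble))
  x
}

#' Write a configuration to YAML
#'
#' Serializes a `"cmd_config"` so that [load_config()] reproduces it.
#'
#' @param config A `"cmd_config"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "cmd_config"))
  sim <- unclass(config$sim)
  sim$spec35 <- NULL # population specs round-trip via the R API
  costs <- unclass(config$costs)
  costs$inflation <- purrr::transpose(as.list(costs$inflation))
  pop <- config$population
  out <- list(
    run = config$run,
    population = list(
      age_bands = purrr::transpose(as.list(pop$age_bands)),
      sex = as.list(pop$sex), race = as.list(pop$race),
      education = as.list(pop$education),
      insurance = as.list(pop$insurance),
      continuous = purrr::transpose(as.list(pop$continuous)),
      prevalence = as.list(pop$prevalence),
      intakes = purrr::transpose(as.list(pop$intakes)),
      weight_shape = pop$weight_shape
    ),
    factors = purrr::transpose(as.list(config$factors)),
    sim = lapply(sim, function(v) if (is.numeric(v) && !is.null(names(v))) as.list(v) else v),
    costs = lapply(costs, function(v) if (is.numeric(v) && !is.null(names(v))) as.list(v) else v),
    payer_mix = purrr::transpose(as.list(config$payer_mix))
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run the full pipeline and write its artifacts
#'
#' Executes generate -> simulate -> attribute -> report from one
#' configuration: generates the synthetic population, runs the
#' single-factor and combined sweep, the stratified tables, the cost-bearer
#' allocation, and (optionally) the Monte-Carlo confidence interval, and
#' writes CSV/JSON artifacts plus a manifest (`manifest.json`) recording
#' the seed, row counts, and an MD5 hash of every output file. Rerunning
#' with the same configuration reproduces every result file byte for byte.
#'
#' @param config A `"cmd_config"` from [load_config()] / `build_config()`.
#' @param out_dir Output directory (created if needed).
#' @param ci Whether to compute the Monte-Carlo confidence interval
#'   (slowest step; default TRUE when `run$ci_draws > 0`).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, ci = config$run$ci_draws > 0) {
  stopifnot(inherits(config, "cmd_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run <- config$run
  seed <- run$seed

  pop <- generate_population(config$population, n = run$n, seed = seed)
  sweep <- per_factor_sweep(pop, config$factors, config$sim, config$costs,
                            seed = seed)
  sim_obs <- run_microsim(pop, scenario_observed(config$factors$factor),
                          config$factors, config$sim, seed)
  sim_cf <- run_microsim(pop, scenario_optimal(config$factors$factor),
                         config$factors, config$sim, seed)
  strata <- purrr::map_dfr(
    c("sex", "age_band", "race", "education", "bmi_band", "insurance"),
    function(v) {
      stratify_costs(sim_obs, sim_cf, config$costs, by = v) |>
        mutate(stratifier = v, .before = 1)
    }
  )
  by_ins <- stratify_costs(sim_obs, sim_cf, config$costs, by = "insurance")
  bearers <- bearer_allocation(
    by_ins |> transmute(insurance = .data$stratum,
                        cost = national_total(.data$total,
                                              run$population_size) *
                          .data$person_time /
                          sum(.data$person_time)),
    config$payer_mix
  )

  combined <- sweep |> filter(.data$scenario == "combined")
  summary <- list(
    n = run$n, seed = seed, horizon = config$sim$horizon,
    per_capita_total = combined$total,
    per_capita_acute = combined$acute,
    per_capita_chronic = combined$chronic_cvd + combined$chronic_diabetes,
    per_capita_drug = combined$drug,
    national_total = national_total(combined$total, run$population_size)
  )
  if (ci) {
    mc <- attribution_ci(pop, config$factors, config$sim, config$costs,
                         n_draws = run$ci_draws, seed = seed)
    summary$ci_lo <- mc$lo
    summary$ci_hi <- mc$hi
  }

  files <- c(
    attribution = "attribution.csv",
    strata = "strata.csv",
    bearers = "cost_bearers.csv",
    summary = "summary.json"
  )
  utils::write.csv(sweep, file.path(out_dir, files["attribution"]),
                   row.names = FALSE)
  utils::write.csv(strata, file.path(out_dir, files["strata"]),
                   row.names = FALSE)
  utils::write.csv(bearers, file.path(out_dir, files["bearers"]),
                   row.names = FALSE)
  jsonlite::write_json(summary, file.path(out_dir, files["summary"]),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(
    created = format(Sys.time(), tz = "UTC"),
    seed = seed, n = run$n,
    outputs = lapply(file.path(out_dir, files), function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)),
           bytes = file.size(f))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}
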
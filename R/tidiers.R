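# broom-style accessors and plots for sweep results.

#' Tidy an attribution sweep
#'
#' One row per scenario-component pair.
#'
#' @param x A `"cmd_attribution"` from [per_factor_sweep()].
#' @param ... Unused.
#' @return A tibble: `scenario`, `component`, `per_capita`.
#' @method tidy cmd_attribution
#' @export
tidy.cmd_attribution <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(
      c("acute", "chronic_cvd", "chronic_diabetes", "drug", "total"),
      names_to = "component", values_to = "per_capita"
    ) |>
    select("scenario", "component", "per_capita")
}

#' One-row summary of an attribution sweep
#'
#' @param x A `"cmd_attribution"`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `horizon`, `combined_total`,
#'   `single_factor_sum`, `n_factors`.
#' @method glance cmd_attribution
#' @export
glance.cmd_attribution <- function(x, ...) {
  singles <- as_tibble(x) |> filter(.data$scenario != "combined")
  combined <- as_tibble(x) |> filter(.data$scenario == "combined")
  tibble(
    n = attr(x, "n"),
    horizon = attr(x, "horizon"),
    combined_total = combined$total,
    single_factor_sum = sum(singles$total),
    n_factors = nrow(singles)
  )
}

#' Plot an attribution sweep
#'
#' Stacked per-capita cost components by scenario, single factors ordered
#' by total attributable cost with the combined scenario last.
#'
#' @param object A `"cmd_attribution"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cmd_attribution
#' @export
autoplot.cmd_attribution <- function(object, ...) {
  df <- tidy(object) |>
    filter(.data$component != "total") |>
    mutate(component = factor(
      .data$component,
      levels = c("acute", "chronic_cvd", "chronic_diabetes", "drug")))
  ord <- as_tibble(object) |> arrange(.data$scenario == "combined",
                                      .data$total)
  df$scenario <- factor(df$scenario, levels = ord$scenario)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario, y = .data$per_capita,
                                   fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Attributable cost (USD/person/year)",
                  fill = "Component") +
    ggplot2::theme_minimal()
}

#' Plot intake distributions of a person table
#'
#' Histograms of the ten intakes with the optimal level marked, a visual
#' check of the generator's calibration.
#'
#' @param table A person table.
#' @param factors Diet-factor table supplying optimal levels.
#' @return A ggplot object.
#' @export
plot_intakes <- function(table, factors = default_diet_factors()) {
  long <- table |>
    select(dplyr::starts_with("intake_")) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "factor",
                        values_to = "intake") |>
    mutate(factor = sub("^intake_", "", .data$factor))
  opt <- factors |> select("factor", "optimal")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$intake)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(data = opt,
                        ggplot2::aes(xintercept = .data$optimal),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~factor, scales = "free") +
    ggplot2::labs(x = "Daily intake", y = "Persons") +
    ggplot2::theme_minimal()
}
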
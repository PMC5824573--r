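#' Tidy a probabilistic sensitivity analysis
#'
#' One row per quantity (`euglycemia`, `gdm`, `delta`) with the Monte Carlo
#' mean, spread and the 10th/90th percentile band (the 80% interval).
#'
#' @param x A `gdm_psa` object from [run_psa()].
#' @param ... Unused.
#' @return A tibble with `group`, `mean`, `sd`, `min`, `p10`, `median`,
#'   `p90`, `max`.
#' @export
tidy.gdm_psa <- function(x, ...) {
  purrr::map(c("euglycemia", "gdm", "delta"), function(g) {
    v <- x$draws[[g]]
    tibble(
      group = g, mean = mean(v), sd = sd(v), min = min(v),
      p10 = unname(quantile(v, 0.10)), median = median(v),
      p90 = unname(quantile(v, 0.90)), max = max(v)
    )
  }) |>
    bind_rows()
}

#' Glance at a probabilistic sensitivity analysis
#'
#' @inheritParams tidy.gdm_psa
#' @return A one-row tibble with the run configuration, the base-case
#'   inpatient costs and the mean and 80% band of the simulated GDM minus
#'   euglycemia difference.
#' @export
glance.gdm_psa <- function(x, ...) {
  s <- tidy(x)
  d <- s[s$group == "delta", ]
  tibble(
    n_iterations = x$n_iterations, seed = x$seed, cost_cv = x$cost_cv,
    probability_source = x$probability_source,
    base_euglycemia = unname(x$base[["euglycemia"]]),
    base_gdm = unname(x$base[["gdm"]]),
    mean_delta = d$mean, p10_delta = d$p10, p90_delta = d$p90
  )
}

#' Tidy a tornado analysis
#'
#' @param x A `gdm_dsa` object from [tornado()].
#' @param ... Unused.
#' @return One row per parameter with the GDM minus euglycemia difference at
#'   the low and high perturbation and the induced range width, sorted by
#'   decreasing width.
#' @export
tidy.gdm_dsa <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$parameter_id) |>
    summarise(
      delta_low = .data$delta[which.min(.data$rel_change)],
      delta_high = .data$delta[which.max(.data$rel_change)],
      delta_range = .data$delta_range[[1]],
      .groups = "drop"
    ) |>
    arrange(desc(.data$delta_range))
}

#' Glance at a tornado analysis
#'
#' @inheritParams tidy.gdm_dsa
#' @return A one-row tibble with the number of parameters, the base-case
#'   difference and the most influential parameter with its range.
#' @export
glance.gdm_dsa <- function(x, ...) {
  s <- tidy(x)
  base <- attr(x, "base")
  tibble(
    n_parameters = nrow(s),
    base_delta = unname(base[["cost_gdm"]] - base[["cost_euglycemia"]]),
    top_parameter = if (nrow(s)) s$parameter_id[[1]] else NA_character_,
    top_delta_low = if (nrow(s)) s$delta_low[[1]] else NA_real_,
    top_delta_high = if (nrow(s)) s$delta_high[[1]] else NA_real_
  )
}

#' Plot Monte Carlo cost distributions
#'
#' Histograms of the simulated inpatient cost per case in each group, with
#' the deterministic base case marked.
#'
#' @param object A `gdm_psa` object.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gdm_psa <- function(object, bins = 40, ...) {
  draws <- object$draws |>
    tidyr::pivot_longer(c("euglycemia", "gdm"), names_to = "group", values_to = "cost")
  base <- tibble(group = names(object$base), cost = unname(object$base))
  ggplot2::ggplot(draws, ggplot2::aes(x = .data$cost)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey55", colour = "white") +
    ggplot2::geom_vline(
      data = base, ggplot2::aes(xintercept = .data$cost), linetype = "dashed"
    ) +
    ggplot2::facet_wrap(~group, scales = "free_x") +
    ggplot2::labs(
      x = "inpatient cost per case (EUR)", y = "iterations",
      title = sprintf("Monte Carlo cost distribution (%d iterations)", object$n_iterations)
    )
}

#' Plot a tornado diagram
#'
#' Horizontal bars spanning the GDM minus euglycemia cost difference reached
#' at the two perturbation directions, widest on top, with the base-case
#' difference marked.
#'
#' @param object A `gdm_dsa` object from [tornado()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gdm_dsa <- function(object, ...) {
  s <- tidy(object)
  base <- attr(object, "base")
  s$parameter_id <- factor(s$parameter_id, levels = rev(s$parameter_id))
  ggplot2::ggplot(s, ggplot2::aes(y = .data$parameter_id)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$delta_low, xend = .data$delta_high, yend = .data$parameter_id),
      linewidth = 4, colour = "grey50"
    ) +
    ggplot2::geom_vline(
      xintercept = unname(base[["cost_gdm"]] - base[["cost_euglycemia"]]),
      linetype = "dashed"
    ) +
    ggplot2::labs(x = "GDM - euglycemia inpatient cost per case (EUR)", y = NULL)
}

#' Plot a cost per case breakdown
#'
#' Stacked bars of the outpatient, mother inpatient and infant inpatient
#' components for each group.
#'
#' @param object A `gdm_cost_breakdown` from [cost_per_case()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gdm_cost_breakdown <- function(object, ...) {
  x <- as_tibble(object) |>
    filter(.data$group != "delta") |>
    tidyr::pivot_longer(
      c("outpatient", "mother_inpatient", "infant_inpatient"),
      names_to = "component", values_to = "cost"
    )
  ggplot2::ggplot(x, ggplot2::aes(x = .data$group, y = .data$cost, fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "cost per case (EUR)", fill = NULL)
}
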
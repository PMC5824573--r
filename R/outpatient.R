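#' Consumption count for a resource frequency over the model horizon
#'
#' Turns a consumption-frequency specification into a number of consumed
#' units over the horizon. For interval frequencies ("every low-high weeks")
#' the conservative lower bound is used: the widest interval yields the
#' fewest events, `floor((horizon_days / 7) / weeks_high)`. Over 90 days this
#' gives 6 visits for "every 1-2 weeks", 3 for "every 3-4 weeks" and 2 for
#' "every 5-6 weeks".
#'
#' @param kind Frequency kind: `"per_day"`, `"per_horizon"`,
#'   `"interval_weeks"` or `"none"` (vectorised).
#' @param horizon_days Modelling horizon in days (scalar, > 0).
#' @param value Units per day (`per_day`) or total units (`per_horizon`).
#' @param weeks_low,weeks_high Interval bounds in weeks (`interval_weeks`).
#' @return A numeric vector of unit counts.
#' @examples
#' consumption_count("per_day", 90, value = 2)
#' consumption_count("interval_weeks", 90, weeks_low = 1, weeks_high = 2)
#' @export
consumption_count <- function(kind, horizon_days, value = NA_real_,
                              weeks_low = NA_real_, weeks_high = NA_real_) {
  stopifnot(length(horizon_days) == 1, horizon_days > 0)
  k <- length(kind)
  value <- rep_len(value, k)
  weeks_high <- rep_len(weeks_high, k)
  unknown <- setdiff(unique(kind), c("per_day", "per_horizon", "interval_weeks", "none"))
  if (length(unknown)) {
    abort(sprintf("unknown frequency kind: '%s'", unknown[[1]]))
  }
  out <- numeric(k)
  out[kind == "per_day"] <- value[kind == "per_day"] * horizon_days
  out[kind == "per_horizon"] <- value[kind == "per_horizon"]
  ivl <- kind == "interval_weeks"
  out[ivl] <- floor((horizon_days / 7) / weeks_high[ivl])
  out[kind == "none"] <- 0
  out
}

#' Antenatal outpatient costs per resource item
#'
#' Expands the outpatient resource table of a parameter set into per-item
#' consumption counts and costs over the model horizon, one row per item and
#' treatment group.
#'
#' @param params A [gdm_params] object.
#' @return A tibble with columns `group`, `item`, `unit_cost`, `n_units`,
#'   `cost`.
#' @examples
#' outpatient_costs(default_parameters())
#' @export
outpatient_costs <- function(params) {
  params$resources |>
    mutate(
      n_units = consumption_count(
        .data$freq_kind, params$population$horizon_days,
        .data$freq_value, .data$weeks_low, .data$weeks_high
      ),
      cost = .data$unit_cost * .data$n_units
    ) |>
    select("group", "item", "unit_cost", "n_units", "cost")
}

#' Antenatal outpatient cost totals per group
#'
#' Sums per-item outpatient costs for each treatment group and appends the
#' insulin-share-weighted GDM average (`group = "gdm"`), the weighted sum of
#' the diet- and insulin-treated costs.
#'
#' @param params A [gdm_params] object.
#' @return A tibble with columns `group` (euglycemia, gdm_diet, gdm_insulin,
#'   gdm) and `total` (EUR per case).
#' @examples
#' outpatient_totals(default_parameters())
#' @export
outpatient_totals <- function(params) {
  by_group <- outpatient_costs(params) |>
    group_by(.data$group) |>
    summarise(total = sum(.data$cost), .groups = "drop")
  totals <- tibble(group = .groups3) |>
    left_join(by_group, by = "group") |>
    mutate(total = ifelse(is.na(.data$total), 0, .data$total))
  gdm <- weighted_gdm_outpatient(
    diet = totals$total[totals$group == "gdm_diet"],
    insulin = totals$total[totals$group == "gdm_insulin"],
    insulin_share = params$population$insulin_share
  )
  bind_rows(totals, tibble(group = "gdm", total = gdm))
}

#' Insulin-share-weighted GDM outpatient cost
#'
#' @param diet Outpatient cost per diet-treated GDM case (EUR).
#' @param insulin Outpatient cost per insulin-treated GDM case (EUR).
#' @param insulin_share Proportion of GDM pregnancies treated with insulin,
#'   in `[0, 1]`.
#' @return `(1 - insulin_share) * diet + insulin_share * insulin`.
#' @examples
#' weighted_gdm_outpatient(262.5, 1034.6, 0.14)
#' @export
weighted_gdm_outpatient <- function(diet, insulin, insulin_share) {
  if (insulin_share < 0 || insulin_share > 1) {
    abort("insulin_share must be in [0, 1]")
  }
  (1 - insulin_share) * diet + insulin_share * insulin
}
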
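#' Discharge records
#'
#' Hospital discharge records are plain tibbles with one row per admission
#' and columns `admission_id`, `patient_id` (may be `NA`: not every record
#' carries a unique ID), `role` (`"mother"` / `"infant"`), `drg` (DRG code,
#' character), `icd9` (semicolon-separated ICD9-CM diagnosis codes, any
#' position), `los_days` (length of stay, >= 1), `admission_day` (ordinal
#' day index) and `tariff` (EUR).
#'
#' @name discharge_records
NULL

record_columns <- c(
  "admission_id", "patient_id", "role", "drg", "icd9",
  "los_days", "admission_day", "tariff"
)

check_records <- function(records) {
  missing <- setdiff(record_columns, names(records))
  if (length(missing)) {
    abort(sprintf("discharge records lack column(s): %s", paste(missing, collapse = ", ")))
  }
  invisible(records)
}

#' Read or write a discharge-record CSV
#'
#' The CSV dialect has one column per [discharge_records] field, with the
#' `icd9` list serialised as a semicolon-separated string.
#'
#' @param path File path.
#' @param records A [discharge_records] tibble.
#' @return `read_discharge_records()` returns a tibble;
#'   `write_discharge_records()` returns `path` invisibly.
#' @export
read_discharge_records <- function(path) {
  records <- readr::read_csv(
    path,
    col_types = readr::cols(
      admission_id = "c", patient_id = "c", role = "c", drg = "c", icd9 = "c",
      los_days = "d", admission_day = "d", tariff = "d"
    )
  )
  records$icd9[is.na(records$icd9)] <- ""
  check_records(records)
}

#' @rdname read_discharge_records
#' @export
write_discharge_records <- function(records, path) {
  readr::write_csv(check_records(records), path)
  invisible(path)
}

#' Identify delivery admissions
#'
#' Keeps mother admissions whose DRG code is one of the six delivery codes
#' (370-375). Childbirth admissions with other DRG codes (recognised by a
#' childbirth ICD9 code) are excluded from the delivery analysis; their count
#' is attached as the `n_excluded` attribute.
#'
#' @param records A [discharge_records] tibble (mother role).
#' @param childbirth_codes ICD9 codes that mark a childbirth admission when
#'   the DRG is outside 370-375.
#' @return The delivery subset, with attribute `n_excluded`.
#' @export
identify_deliveries <- function(records, childbirth_codes = c("650", "V27.0")) {
  check_records(records)
  mothers <- records[records$role == "mother", ]
  is_delivery <- mothers$drg %in% .drg_codes
  other_childbirth <- !is_delivery & icd9_has(mothers$icd9, childbirth_codes)
  out <- mothers[is_delivery, ]
  attr(out, "n_excluded") <- sum(other_childbirth)
  out
}

#' Flag GDM delivery admissions
#'
#' A delivery admission is flagged as GDM if the diagnosis code 648.8
#' (abnormal glucose tolerance in pregnancy) appears among its own ICD9
#' codes, or among the codes of any admission of the same patient within the
#' look-back window before the delivery (admission day in
#' `[delivery_day - lookback_days, delivery_day)`). Records without a
#' patient ID cannot be linked and can only be flagged through the birth
#' admission itself.
#'
#' @param records All available [discharge_records] (the look-back pool).
#' @param deliveries The delivery subset from [identify_deliveries()].
#' @param lookback_days Look-back window length in days (default 90).
#' @param gdm_code The flagging ICD9 code.
#' @return A tibble with columns `admission_id`, `gdm` (logical), one row
#'   per delivery.
#' @export
flag_gdm <- function(records, deliveries, lookback_days = 90, gdm_code = "648.8") {
  check_records(records)
  own <- icd9_has(deliveries$icd9, gdm_code)
  pool <- records[icd9_has(records$icd9, gdm_code) & !is.na(records$patient_id), ]
  linked <- deliveries |>
    select("admission_id", "patient_id", "admission_day") |>
    filter(!is.na(.data$patient_id)) |>
    inner_join(
      pool |> select("patient_id", prior_day = "admission_day"),
      by = "patient_id", relationship = "many-to-many"
    ) |>
    filter(
      .data$prior_day < .data$admission_day,
      .data$prior_day >= .data$admission_day - lookback_days
    ) |>
    distinct(.data$admission_id)
  tibble(
    admission_id = deliveries$admission_id,
    gdm = own | deliveries$admission_id %in% linked$admission_id
  )
}

flag_group <- function(deliveries, gdm_flags) {
  check_records(deliveries) |>
    inner_join(gdm_flags, by = "admission_id") |>
    mutate(group = ifelse(.data$gdm, "gdm", "euglycemia"))
}

#' Estimate the delivery mix from flagged deliveries
#'
#' Counts delivery admissions per DRG category within each group and
#' normalises the counts to probabilities.
#'
#' @param deliveries Delivery subset from [identify_deliveries()].
#' @param gdm_flags Flags from [flag_gdm()].
#' @return A tibble with `drg`, `group`, `n`, `prob`.
#' @export
estimate_delivery_mix <- function(deliveries, gdm_flags) {
  x <- flag_group(deliveries, gdm_flags)
  groups <- unique(x$group)
  if (!all(.groups2 %in% groups)) {
    abort(sprintf(
      "group '%s' has zero deliveries", setdiff(.groups2, groups)[[1]]
    ))
  }
  tidyr::expand_grid(drg = .drg_codes, group = .groups2) |>
    left_join(
      x |> group_by(.data$drg, .data$group) |> summarise(n = n(), .groups = "drop"),
      by = c("drg", "group")
    ) |>
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n)) |>
    group_by(.data$group) |>
    mutate(prob = .data$n / sum(.data$n)) |>
    ungroup() |>
    arrange(.data$drg, .data$group)
}

# nearest-rank percentile: value at position ceiling(q * n) of the sorted LOS
nearest_rank <- function(x, q) {
  sort(x)[ceiling(q * length(x))]
}

#' Length-of-stay-adjusted delivery cost per group
#'
#' Implements tariff costing adjusted for length of stay (LOS). Within each
#' DRG category, admissions with a LOS strictly above the category's
#' 99th-percentile LOS (nearest-rank; ties at the threshold retained) are
#' excluded as outliers; the cost per admission day is the official tariff
#' divided by the mean LOS across all remaining women in the category; the
#' group cost is that daily cost times the group's mean LOS.
#'
#' @param deliveries Delivery subset from [identify_deliveries()].
#' @param gdm_flags Flags from [flag_gdm()].
#' @param tariffs Named numeric vector of official DRG tariffs (EUR), names
#'   are DRG codes.
#' @param outlier_quantile LOS percentile above which admissions are
#'   excluded (default 0.99).
#' @return A tibble with one row per `drg` and `group`: `n_total`, `n_kept`,
#'   `n_excluded`, `mean_los`, `daily_cost`, `cost`.
#' @export
los_adjusted_cost <- function(deliveries, gdm_flags, tariffs, outlier_quantile = 0.99) {
  x <- flag_group(deliveries, gdm_flags)
  missing <- setdiff(unique(x$drg), names(tariffs))
  if (length(missing)) {
    abort(sprintf("no tariff supplied for DRG %s", paste(missing, collapse = ", ")))
  }
  purrr::map(split(x, x$drg), function(cat) {
    threshold <- nearest_rank(cat$los_days, outlier_quantile)
    kept <- cat[cat$los_days <= threshold, ]
    if (!nrow(kept)) abort(sprintf("DRG %s has no admissions after outlier exclusion", cat$drg[[1]]))
    daily <- unname(tariffs[[cat$drg[[1]]]]) / mean(kept$los_days)
    totals <- cat |>
      group_by(.data$group) |>
      summarise(n_total = n(), .groups = "drop")
    kept |>
      group_by(.data$group) |>
      summarise(n_kept = n(), mean_los = mean(.data$los_days), .groups = "drop") |>
      left_join(totals, by = "group") |>
      mutate(
        drg = cat$drg[[1]],
        n_excluded = .data$n_total - .data$n_kept,
        daily_cost = daily,
        cost = daily * .data$mean_los
      ) |>
      select(
        "drg", "group", "n_total", "n_kept", "n_excluded",
        "mean_los", "daily_cost", "cost"
      )
  }) |>
    bind_rows() |>
    arrange(.data$drg, .data$group)
}

default_complication_codes <- function() {
  list(
    hypoglycemia = c("775.0", "775.6"),
    hyperbilirubinemia = c("774.2", "774.6"),
    shoulder_dystocia = "660.4",
    respiratory_distress = "769",
    brachial_plexus_injury = "767.6"
  )
}

#' Mean admission cost per neonatal complication
#'
#' For each complication, averages the reimbursement tariff over all infant
#' admissions whose diagnosis codes contain any of the complication's ICD9
#' codes (in any position). Codes mapped to the same model outcome (e.g.
#' 775.0/775.6 for hypoglycemia) are pooled. An admission carrying the codes
#' of several complications contributes to each of their means. Outcomes with
#' no matching admission are reported with `n_admissions = 0` and a missing
#' mean, never as zero cost.
#'
#' @param infant_records Infant [discharge_records].
#' @param complication_codes Named list mapping outcome name to ICD9 code
#'   vector; defaults to the packaged neonatal complication map.
#' @return A tibble with `outcome`, `codes`, `n_admissions`, `mean_cost`.
#' @export
infant_event_costs <- function(infant_records,
                               complication_codes = default_complication_codes()) {
  check_records(infant_records)
  x <- infant_records[infant_records$role == "infant", ]
  purrr::imap(complication_codes, function(cc, outcome) {
    hit <- icd9_has(x$icd9, cc)
    tibble(
      outcome = outcome,
      codes = paste(cc, collapse = ";"),
      n_admissions = sum(hit),
      mean_cost = if (any(hit)) mean(x$tariff[hit]) else NA_real_
    )
  }) |>
    bind_rows()
}

#' Extract model parameters from discharge records
#'
#' Runs the full extraction pipeline — delivery identification, GDM
#' flagging with look-back linkage, delivery-mix estimation and
#' LOS-adjusted tariff costing — and installs the estimates into a copy of
#' `base_params`, closing the loop from raw discharge records to a runnable
#' cost model. If infant records are supplied, extracted complication costs
#' replace the corresponding outcome costs (neonatal outcome probabilities
#' always stay at their literature-derived values: mothers and infants
#' cannot be linked in the discharge data).
#'
#' @param mother_records Mother [discharge_records].
#' @param tariffs Named numeric vector of official DRG tariffs.
#' @param infant_records Optional infant [discharge_records].
#' @param base_params Parameter set supplying everything that is not
#'   extracted (defaults to [default_parameters()]).
#' @param lookback_days,outlier_quantile See [flag_gdm()],
#'   [los_adjusted_cost()].
#' @return A validated [gdm_params] object with the extracted delivery mix,
#'   delivery costs and (optionally) outcome costs.
#' @export
extract_model_parameters <- function(mother_records, tariffs,
                                     infant_records = NULL,
                                     base_params = default_parameters(),
                                     lookback_days = 90,
                                     outlier_quantile = 0.99) {
  deliveries <- identify_deliveries(mother_records)
  flags <- flag_gdm(mother_records, deliveries, lookback_days)
  mix <- estimate_delivery_mix(deliveries, flags)
  costs <- los_adjusted_cost(deliveries, flags, tariffs, outlier_quantile)
  p <- base_params
  key_p <- paste(p$delivery$drg, p$delivery$group)
  mix_idx <- match(key_p, paste(mix$drg, mix$group))
  cost_idx <- match(key_p, paste(costs$drg, costs$group))
  p$delivery$count <- as.numeric(mix$n[mix_idx])
  p$delivery$prob <- mix$prob[mix_idx]
  # a category-group cell with no observed admissions has probability zero
  # and no estimable cost; the base cost is kept (it cannot affect the
  # expected cost through a zero-probability branch)
  new_cost <- costs$cost[cost_idx]
  p$delivery$cost <- ifelse(is.na(new_cost), p$delivery$cost, new_cost)
  if (!is.null(infant_records)) {
    ev <- infant_event_costs(infant_records)
    found <- ev[!is.na(ev$mean_cost), ]
    i <- match(found$outcome, p$outcome_costs$outcome)
    p$outcome_costs$cost[i] <- found$mean_cost
  }
  stop_if_invalid(p)
}
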
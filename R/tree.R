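#' Expected inpatient delivery cost for the mother
#'
#' The probability-weighted mean of the six DRG delivery-category costs for a
#' mother group: the sum of the products of category probabilities and
#' per-admission costs.
#'
#' @param params A [gdm_params] object.
#' @param group `"euglycemia"` or `"gdm"`.
#' @return Expected cost per case (EUR), a scalar.
#' @examples
#' mother_inpatient_cost(default_parameters(), "gdm")
#' @export
mother_inpatient_cost <- function(params, group = c("euglycemia", "gdm")) {
  group <- match.arg(group)
  d <- params$delivery[params$delivery$group == group, ]
  sum(d$prob * d$cost)
}

#' Expected inpatient cost for the infant
#'
#' The neonatal branch of the cost tree: macrosomia (birthweight >= 4 kg)
#' splits each group, and within each macrosomia status the infant experiences
#' exactly one of the model outcomes (including "normal newborn"), each with
#' its admission cost. The expected cost is
#' `p_macro * E[cost | macro] + (1 - p_macro) * E[cost | no macro]`.
#'
#' @inheritParams mother_inpatient_cost
#' @return Expected cost per case (EUR), a scalar.
#' @examples
#' infant_inpatient_cost(default_parameters(), "euglycemia")
#' @export
infant_inpatient_cost <- function(params, group = c("euglycemia", "gdm")) {
  group <- match.arg(group)
  pm <- params$macrosomia$prob[params$macrosomia$group == group]
  br <- params$outcomes[params$outcomes$group == group, ] |>
    left_join(params$outcome_costs, by = "outcome")
  ev <- function(macro) {
    rows <- br[br$macrosomia == macro, ]
    sum(rows$prob * rows$cost)
  }
  pm * ev(TRUE) + (1 - pm) * ev(FALSE)
}

#' Cost per case breakdown
#'
#' Assembles the full cost per case for euglycemic and GDM pregnancies:
#' antenatal outpatient cost (insulin-share-weighted for GDM), expected
#' mother inpatient delivery cost, expected infant inpatient cost, their
#' inpatient subtotal and the overall total, plus a `delta` row with the
#' GDM minus euglycemia difference of every component.
#'
#' @param params A [gdm_params] object.
#' @return A tibble of class `gdm_cost_breakdown` with rows `euglycemia`,
#'   `gdm`, `delta` and columns `outpatient`, `mother_inpatient`,
#'   `infant_inpatient`, `inpatient_total`, `total` (EUR per case).
#' @examples
#' cost_per_case(default_parameters())
#' @export
cost_per_case <- function(params) {
  stop_if_invalid(params)
  out <- outpatient_totals(params)
  op <- c(
    euglycemia = out$total[out$group == "euglycemia"],
    gdm = out$total[out$group == "gdm"]
  )
  rows <- purrr::map(.groups2, function(g) {
    m <- mother_inpatient_cost(params, g)
    i <- infant_inpatient_cost(params, g)
    tibble(
      group = g, outpatient = op[[g]], mother_inpatient = m, infant_inpatient = i,
      inpatient_total = m + i, total = op[[g]] + m + i
    )
  })
  x <- bind_rows(rows)
  delta <- x[x$group == "gdm", -1] - x[x$group == "euglycemia", -1]
  x <- bind_rows(x, bind_cols(tibble(group = "delta"), delta))
  class(x) <- c("gdm_cost_breakdown", class(x))
  x
}

#' National annual burden of GDM
#'
#' Scales the per-case cost difference to the national level: the number of
#' GDM cases is the annual number of births times the GDM prevalence (rounded
#' half-up to a whole case count), and the incremental burden is that case
#' count times the GDM minus euglycemia total cost difference.
#'
#' @param params A [gdm_params] object.
#' @param breakdown Optionally, a precomputed [cost_per_case()] result for
#'   `params`.
#' @return A one-row tibble with `gdm_cases`, `incremental_cost` (EUR) and
#'   `relative_increase` (GDM vs euglycemia total cost ratio minus one).
#' @examples
#' national_burden(default_parameters())
#' @export
national_burden <- function(params, breakdown = NULL) {
  breakdown <- breakdown %||% cost_per_case(params)
  cases <- round_half_up(params$population$births * params$population$gdm_prevalence)
  delta_total <- breakdown$total[breakdown$group == "delta"]
  eug_total <- breakdown$total[breakdown$group == "euglycemia"]
  tibble(
    gdm_cases = cases,
    incremental_cost = cases * delta_total,
    relative_increase = delta_total / eug_total
  )
}

#' Enumerate the terminal leaves of the cost tree
#'
#' Exhaustively lists every terminal node of the inpatient cost tree for one
#' group: the six delivery leaves (one branch system) and the twelve
#' macrosomia-by-outcome infant leaves (a second branch system), each with
#' its joint probability and cost. The probability-weighted cost summed over
#' all leaves equals the closed-form mother plus infant expected inpatient
#' cost, which makes this a brute-force cross-check of the analytic sums.
#'
#' @inheritParams mother_inpatient_cost
#' @return A tibble with columns `system` (`"delivery"` or `"infant"`),
#'   `label`, `probability`, `cost`.
#' @examples
#' leaves <- enumerate_tree(default_parameters(), "gdm")
#' sum(leaves$probability * leaves$cost)
#' @export
enumerate_tree <- function(params, group = c("euglycemia", "gdm")) {
  group <- match.arg(group)
  d <- params$delivery[params$delivery$group == group, ]
  delivery <- tibble(
    system = "delivery",
    label = paste0("DRG ", d$drg, ": ", d$description),
    probability = d$prob,
    cost = d$cost
  )
  pm <- params$macrosomia$prob[params$macrosomia$group == group]
  br <- params$outcomes[params$outcomes$group == group, ] |>
    left_join(params$outcome_costs, by = "outcome")
  infant <- tibble(
    system = "infant",
    label = paste0(ifelse(br$macrosomia, "macrosomia", "no macrosomia"), " / ", br$outcome),
    probability = ifelse(br$macrosomia, pm, 1 - pm) * br$prob,
    cost = br$cost
  )
  bind_rows(delivery, infant)
}
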
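#' Model parameters
#'
#' A `gdm_params` object bundles every input of the cost model as a set of
#' tibbles plus a small population list:
#'
#' * `resources` — antenatal outpatient resource items, one row per item and
#'   consuming treatment group (`euglycemia`, `gdm_diet`, `gdm_insulin`), with
#'   the unit cost (EUR) and a consumption-frequency specification
#'   (`freq_kind` one of `per_day`, `per_horizon`, `interval_weeks`, `none`).
#' * `delivery` — the six DRG delivery categories (370-375), one row per
#'   category and mother group (`euglycemia`, `gdm`), with admission counts
#'   (where known), the category probability and the per-admission cost (EUR).
#'   Probabilities are stored as exact count ratios when counts are available,
#'   so derived quantities are not degraded by the rounding of printed
#'   percentages.
#' * `macrosomia` — probability of macrosomia (birthweight >= 4 kg) per group.
#' * `outcomes` — neonatal outcome probabilities conditional on group and
#'   macrosomia status. The `normal_newborn` probability is always computed by
#'   difference so each conditional vector sums to one.
#' * `outcome_costs` — one admission cost (EUR) per neonatal outcome,
#'   group-independent.
#' * `population` — `insulin_share` (proportion of GDM pregnancies treated
#'   with insulin), `horizon_days` (modelling horizon, days),
#'   `births` (annual births) and `gdm_prevalence`.
#'
#' @name gdm_params
NULL

# The default configuration: the packaged national base case.
# Counts, unit costs, probabilities and tariffs are the published Italian
# 2014 values (HDD delivery counts, national tariff list, literature-derived
# neonatal outcome probabilities).
default_config <- function() {
  list(
    population = list(
      insulin_share = 0.14,
      horizon_days = 90,
      births = 502596,
      gdm_prevalence = 0.109
    ),
    outpatient = list(
      ogtt_75g = list(
        unit_cost = 2.38,
        gdm_diet = list(kind = "per_horizon", count = 2),
        gdm_insulin = list(kind = "per_horizon", count = 2),
        euglycemia = list(kind = "per_horizon", count = 1)
      ),
      glucometer = list(
        unit_cost = 0,
        gdm_diet = list(kind = "per_horizon", count = 1),
        gdm_insulin = list(kind = "per_horizon", count = 1)
      ),
      test_strip = list(
        unit_cost = 0.55,
        gdm_diet = list(kind = "per_day", per_day = 2),
        gdm_insulin = list(kind = "per_day", per_day = 4)
      ),
      finger_stick = list(
        unit_cost = 0.10,
        gdm_diet = list(kind = "per_day", per_day = 2),
        gdm_insulin = list(kind = "per_day", per_day = 4)
      ),
      insulin_shot = list(
        unit_cost = 6.34,
        gdm_insulin = list(kind = "per_day", per_day = 1)
      ),
      needle = list(
        unit_cost = 0.14,
        gdm_insulin = list(kind = "per_day", per_day = 1)
      ),
      syringe = list(
        unit_cost = 0.11,
        gdm_insulin = list(kind = "per_day", per_day = 1)
      ),
      obstetric_visit = list(
        unit_cost = 20.66,
        gdm_diet = list(kind = "interval_weeks", low = 3, high = 4),
        gdm_insulin = list(kind = "interval_weeks", low = 1, high = 2),
        euglycemia = list(kind = "interval_weeks", low = 5, high = 6)
      ),
      obstetric_ultrasound = list(
        unit_cost = 30.99,
        gdm_diet = list(kind = "per_horizon", count = 2),
        gdm_insulin = list(kind = "per_horizon", count = 2)
      ),
      visual_field_test = list(
        unit_cost = 16.78,
        gdm_diet = list(kind = "per_horizon", count = 1),
        gdm_insulin = list(kind = "per_horizon", count = 1)
      )
    ),
    delivery = list(
      drg_370 = list(
        description = "Caesarean section with CC",
        euglycemia = list(count = 11437, cost = 2774.5),
        gdm = list(count = 538, cost = 2938.5)
      ),
      drg_371 = list(
        description = "Caesarean section without CC",
        euglycemia = list(count = 145212, cost = 2084.3),
        gdm = list(count = 4019, cost = 2373.0)
      ),
      drg_372 = list(
        description = "Vaginal delivery with CC",
        euglycemia = list(count = 9447, cost = 1610.3),
        gdm = list(count = 447, cost = 1802.8)
      ),
      drg_373 = list(
        description = "Vaginal delivery without CC",
        euglycemia = list(count = 260036, cost = 1269.3),
        gdm = list(count = 6287, cost = 1385.2)
      ),
      drg_374 = list(
        description = "Vaginal delivery with sterilization and/or D&C",
        euglycemia = list(count = 4274, cost = 2116.0),
        gdm = list(count = 125, cost = 2330.9)
      ),
      drg_375 = list(
        description = "Vaginal delivery with other intervention",
        euglycemia = list(count = 445, cost = 2842.0),
        gdm = list(count = 18, cost = 3265.9)
      )
    ),
    infant = list(
      macrosomia = list(euglycemia = 0.074, gdm = 0.087),
      outcomes = list(
        hypoglycemia = list(
          cost = 6571.8,
          euglycemia = list(macrosomia = 0.024, no_macrosomia = 0.012),
          gdm = list(macrosomia = 0.053, no_macrosomia = 0.026)
        ),
        hyperbilirubinemia = list(
          cost = 2854.2,
          euglycemia = list(macrosomia = 0.076, no_macrosomia = 0.091),
          gdm = list(macrosomia = 0.132, no_macrosomia = 0.104)
        ),
        shoulder_dystocia = list(
          cost = 1407.6,
          euglycemia = list(macrosomia = 0.060, no_macrosomia = 0.009),
          gdm = list(macrosomia = 0.105, no_macrosomia = 0.016)
        ),
        respiratory_distress = list(
          cost = 24337.8,
          euglycemia = list(macrosomia = 0.017, no_macrosomia = 0.012),
          gdm = list(macrosomia = 0.040, no_macrosomia = 0.015)
        ),
        brachial_plexus_injury = list(
          cost = 1671.9,
          euglycemia = list(macrosomia = 0.007, no_macrosomia = 0.001),
          gdm = list(macrosomia = 0.026, no_macrosomia = 0.002)
        ),
        normal_newborn = list(cost = 560.0)
      )
    )
  )
}

build_resources <- function(cfg_out) {
  rows <- purrr::imap(cfg_out, function(item_cfg, item) {
    groups <- intersect(names(item_cfg), .groups3)
    purrr::map(groups, function(g) {
      f <- item_cfg[[g]]
      kind <- f$kind %||% "none"
      tibble(
        item = item,
        unit_cost = as.numeric(item_cfg$unit_cost),
        group = g,
        freq_kind = kind,
        freq_value = switch(kind,
          per_day = as.numeric(f$per_day),
          per_horizon = as.numeric(f$count),
          NA_real_
        ),
        weeks_low = if (kind == "interval_weeks") as.numeric(f$low) else NA_real_,
        weeks_high = if (kind == "interval_weeks") as.numeric(f$high) else NA_real_
      )
    })
  })
  bind_rows(purrr::flatten(rows))
}

build_delivery <- function(cfg_del) {
  rows <- purrr::imap(cfg_del, function(d, key) {
    purrr::map(.groups2, function(g) {
      tibble(
        drg = sub("^drg_", "", key),
        description = d$description,
        group = g,
        count = as.numeric(d[[g]]$count %||% NA_real_),
        prob_given = as.numeric(d[[g]]$prob %||% NA_real_),
        cost = as.numeric(d[[g]]$cost)
      )
    })
  })
  bind_rows(purrr::flatten(rows)) |>
    group_by(.data$group) |>
    mutate(prob = ifelse(
      !is.na(.data$prob_given),
      .data$prob_given,
      .data$count / sum(.data$count, na.rm = TRUE)
    )) |>
    ungroup() |>
    select(-"prob_given")
}

build_infant <- function(cfg_inf) {
  macro <- tibble(
    group = .groups2,
    prob = unname(vapply(.groups2, function(g) as.numeric(cfg_inf$macrosomia[[g]]), numeric(1)))
  )
  named <- setdiff(names(cfg_inf$outcomes), "normal_newborn")
  grid <- expand.grid(
    outcome = named, group = .groups2, macrosomia = c(TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  grid$prob <- mapply(function(o, g, m) {
    as.numeric(cfg_inf$outcomes[[o]][[g]][[if (m) "macrosomia" else "no_macrosomia"]])
  }, grid$outcome, grid$group, grid$macrosomia)
  outcomes <- as_tibble(grid)
  # normal newborn: complement within each group x macrosomia branch
  normal <- outcomes |>
    group_by(.data$group, .data$macrosomia) |>
    summarise(prob = 1 - sum(.data$prob), .groups = "drop") |>
    mutate(outcome = "normal_newborn")
  outcomes <- bind_rows(outcomes, normal) |>
    mutate(outcome = factor(.data$outcome, levels = .outcomes)) |>
    arrange(.data$group, desc(.data$macrosomia), .data$outcome) |>
    mutate(outcome = as.character(.data$outcome))
  costs <- tibble(
    outcome = names(cfg_inf$outcomes),
    cost = unname(vapply(cfg_inf$outcomes, function(o) as.numeric(o$cost), numeric(1)))
  )
  list(macrosomia = macro, outcomes = outcomes, outcome_costs = costs)
}

build_parameters <- function(config) {
  inf <- build_infant(config$infant)
  structure(
    list(
      resources = build_resources(config$outpatient),
      delivery = build_delivery(config$delivery),
      macrosomia = inf$macrosomia,
      outcomes = inf$outcomes,
      outcome_costs = inf$outcome_costs,
      population = lapply(config$population, as.numeric)
    ),
    class = "gdm_params"
  )
}

#' Default model parameters
#'
#' Returns the packaged base-case parameter set: antenatal outpatient resource
#' items and unit costs, the six-category delivery mix per mother group with
#' admission counts and tariff-based costs, macrosomia-stratified neonatal
#' outcome probabilities and costs, and the population inputs (14% insulin
#' share, 90-day horizon, 502,596 births, 10.9% GDM prevalence).
#'
#' @return A [gdm_params] object.
#' @examples
#' p <- default_parameters()
#' p$population$gdm_prevalence
#' @export
default_parameters <- function() {
  build_parameters(default_config())
}

#' @export
print.gdm_params <- function(x, ...) {
  cat("<gdm_params>\n")
  cat(sprintf(
    "  horizon %d days | births %d | GDM prevalence %.1f%% | insulin share %.0f%%\n",
    as.integer(x$population$horizon_days), as.integer(x$population$births),
    100 * x$population$gdm_prevalence, 100 * x$population$insulin_share
  ))
  cat(sprintf(
    "  %d outpatient resource rows, %d delivery rows, %d neonatal outcome rows\n",
    nrow(x$resources), nrow(x$delivery), nrow(x$outcomes)
  ))
  v <- validate_parameters(x)
  if (length(v)) cat("  INVALID:", length(v), "violation(s); see validate_parameters()\n")
  invisible(x)
}

# ---- validation -------------------------------------------------------------

#' Validate a parameter set
#'
#' Checks every structural invariant of a [gdm_params] object and reports the
#' violations instead of raising, so all problems can be listed at once.
#'
#' @param params A [gdm_params] object.
#' @return A character vector of violation descriptions; empty when the
#'   parameter set is valid.
#' @examples
#' validate_parameters(default_parameters())
#' @export
validate_parameters <- function(params) {
  v <- character()
  say <- function(...) v <<- c(v, sprintf(...))

  r <- params$resources
  bad <- r$unit_cost < 0
  if (any(bad)) say("resources: negative unit_cost for item '%s'", r$item[bad])
  bad <- !r$group %in% .groups3
  if (any(bad)) say("resources: unknown group '%s' for item '%s'", r$group[bad], r$item[bad])
  bad <- !r$freq_kind %in% c("per_day", "per_horizon", "interval_weeks", "none")
  if (any(bad)) say("resources: unknown frequency kind '%s' (item '%s')", r$freq_kind[bad], r$item[bad])
  bad <- r$freq_kind == "per_day" & (is.na(r$freq_value) | r$freq_value <= 0)
  if (any(bad)) say("resources: per_day frequency must be > 0 (item '%s')", r$item[bad])
  bad <- r$freq_kind == "interval_weeks" &
    (is.na(r$weeks_low) | is.na(r$weeks_high) | r$weeks_low > r$weeks_high | r$weeks_low <= 0)
  if (any(bad)) say("resources: invalid weeks interval (item '%s')", r$item[bad])

  d <- params$delivery
  bad <- is.na(d$prob) | d$prob < 0 | d$prob > 1
  if (any(bad)) say("delivery: probability missing or outside [0,1] (DRG %s, %s)", d$drg[bad], d$group[bad])
  bad <- is.na(d$cost) | d$cost <= 0
  if (any(bad)) say("delivery: cost must be > 0 (DRG %s, %s)", d$drg[bad], d$group[bad])
  sums <- d |>
    group_by(.data$group) |>
    summarise(s = sum(.data$prob), k = n(), .groups = "drop")
  bad <- abs(sums$s - 1) > 1e-9
  if (any(bad & !is.na(sums$s))) {
    say("delivery: probabilities for group '%s' sum to %.6f, not 1", sums$group[bad], sums$s[bad])
  }
  bad <- sums$k != 6
  if (any(bad)) say("delivery: group '%s' has %d categories, expected 6", sums$group[bad], sums$k[bad])

  m <- params$macrosomia
  bad <- m$prob < 0 | m$prob > 1
  if (any(bad)) say("infant_model: macrosomia probability outside [0,1] (group %s)", m$group[bad])

  o <- params$outcomes
  bad <- o$prob < 0 | o$prob > 1
  if (any(bad)) {
    say(
      "infant_model: outcome probability outside [0,1] ('%s', %s, %s)",
      o$outcome[bad], o$group[bad], ifelse(o$macrosomia[bad], "macrosomia", "no macrosomia")
    )
  }
  osum <- o |>
    group_by(.data$group, .data$macrosomia) |>
    summarise(s = sum(.data$prob), .groups = "drop")
  bad <- abs(osum$s - 1) > 1e-9
  if (any(bad)) {
    say(
      "infant_model: outcome probabilities (%s, %s) sum to %.6f, not 1",
      osum$group[bad], ifelse(osum$macrosomia[bad], "macrosomia", "no macrosomia"), osum$s[bad]
    )
  }
  oc <- params$outcome_costs
  bad <- is.na(oc$cost) | oc$cost <= 0
  if (any(bad)) say("infant_model: outcome cost must be > 0 ('%s')", oc$outcome[bad])

  pop <- params$population
  if (pop$insulin_share < 0 || pop$insulin_share > 1) say("population: insulin_share outside [0,1]")
  if (pop$gdm_prevalence < 0 || pop$gdm_prevalence > 1) say("population: gdm_prevalence outside [0,1]")
  if (pop$horizon_days <= 0) say("population: horizon_days must be > 0")
  if (pop$births <= 0) say("population: births must be > 0")
  v
}

stop_if_invalid <- function(params) {
  v <- validate_parameters(params)
  if (length(v)) {
    abort(c("invalid model parameters", setNames(v, rep("x", length(v)))))
  }
  invisible(params)
}

# ---- config file IO ---------------------------------------------------------

is_freq_node <- function(x) is.list(x) && !is.null(x$kind)

check_config_keys <- function(user, default, path = "") {
  if (!is.list(user) || length(user) == 0) {
    return(invisible(NULL))
  }
  nm <- names(user)
  if (is.null(nm) || any(!nzchar(nm))) {
    abort(sprintf("configuration error: unnamed entry under '%s'", path))
  }
  # delivery group cells may carry either a count or a direct prob
  if (grepl("^delivery/[^/]+/(euglycemia|gdm)$", path)) {
    extra <- setdiff(nm, c("count", "prob", "cost"))
    if (length(extra)) {
      abort(sprintf("configuration error: unknown key '%s/%s'", path, extra[[1]]))
    }
    return(invisible(NULL))
  }
  for (k in nm) {
    here <- if (nzchar(path)) paste(path, k, sep = "/") else k
    if (is_freq_node(user[[k]])) {
      extra <- setdiff(names(user[[k]]), c("kind", "per_day", "count", "low", "high"))
      if (length(extra)) {
        abort(sprintf("configuration error: unknown key '%s/%s'", here, extra[[1]]))
      }
      next
    }
    if (!k %in% names(default)) {
      abort(sprintf("configuration error: unknown key '%s'", here))
    }
    if (is.list(user[[k]]) && is.list(default[[k]])) {
      check_config_keys(user[[k]], default[[k]], here)
    }
  }
  invisible(NULL)
}

merge_config <- function(default, user) {
  for (k in names(user)) {
    # frequency nodes are replaced wholesale so a changed `kind` does not
    # inherit stale fields from the default
    if (is.list(user[[k]]) && is.list(default[[k]]) && !is_freq_node(user[[k]])) {
      default[[k]] <- merge_config(default[[k]], user[[k]])
    } else {
      default[[k]] <- user[[k]]
    }
  }
  default
}

#' Load model parameters from a YAML configuration file
#'
#' Reads a configuration with (any subset of) the sections `population`,
#' `outpatient`, `delivery` and `infant`, mirroring the layout of
#' [default_parameters()]. Unspecified keys fall back to the packaged
#' defaults; unknown keys raise a configuration error naming the key, and a
#' parameter set violating any model invariant raises a validation error
#' listing every violation. In the `delivery` section each group entry may
#' carry either an admission `count` (probabilities are then the within-group
#' count ratios) or a direct `prob`.
#'
#' @param path Path to a YAML file.
#' @return A validated [gdm_params] object.
#' @seealso [write_parameters()] for the inverse operation.
#' @export
load_parameters <- function(path) {
  user <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) abort(sprintf("configuration error in '%s': %s", path, conditionMessage(e)))
  )
  if (is.null(user) || identical(user, "")) user <- list()
  base <- default_config()
  check_config_keys(user, base)
  # a user-supplied prob overrides the default count for that cell
  for (k in names(user$delivery)) {
    for (g in intersect(names(user$delivery[[k]]), .groups2)) {
      if (!is.null(user$delivery[[k]][[g]]$prob)) base$delivery[[k]][[g]]$count <- NULL
    }
  }
  params <- build_parameters(merge_config(base, user))
  stop_if_invalid(params)
}

params_to_config <- function(params) {
  out <- list()
  for (item in unique(params$resources$item)) {
    rows <- params$resources[params$resources$item == item, ]
    node <- list(unit_cost = rows$unit_cost[[1]])
    for (i in seq_len(nrow(rows))) {
      f <- switch(rows$freq_kind[[i]],
        per_day = list(kind = "per_day", per_day = rows$freq_value[[i]]),
        per_horizon = list(kind = "per_horizon", count = rows$freq_value[[i]]),
        interval_weeks = list(kind = "interval_weeks", low = rows$weeks_low[[i]], high = rows$weeks_high[[i]]),
        none = list(kind = "none")
      )
      node[[rows$group[[i]]]] <- f
    }
    out[[item]] <- node
  }
  del <- list()
  for (code in unique(params$delivery$drg)) {
    rows <- params$delivery[params$delivery$drg == code, ]
    node <- list(description = rows$description[[1]])
    for (i in seq_len(nrow(rows))) {
      cell <- if (!is.na(rows$count[[i]])) {
        list(count = rows$count[[i]], cost = rows$cost[[i]])
      } else {
        list(prob = rows$prob[[i]], cost = rows$cost[[i]])
      }
      node[[rows$group[[i]]]] <- cell
    }
    del[[paste0("drg_", code)]] <- node
  }
  oc <- params$outcomes
  outcomes <- list()
  for (o in setdiff(unique(params$outcome_costs$outcome), "normal_newborn")) {
    node <- list(cost = params$outcome_costs$cost[params$outcome_costs$outcome == o])
    for (g in .groups2) {
      node[[g]] <- list(
        macrosomia = oc$prob[oc$outcome == o & oc$group == g & oc$macrosomia],
        no_macrosomia = oc$prob[oc$outcome == o & oc$group == g & !oc$macrosomia]
      )
    }
    outcomes[[o]] <- node
  }
  outcomes$normal_newborn <- list(
    cost = params$outcome_costs$cost[params$outcome_costs$outcome == "normal_newborn"]
  )
  list(
    population = params$population,
    outpatient = out,
    delivery = del,
    infant = list(
      macrosomia = as.list(setNames(params$macrosomia$prob, params$macrosomia$group)),
      outcomes = outcomes
    )
  )
}

#' Write model parameters to a YAML configuration file
#'
#' Serialises a [gdm_params] object to the same format read by
#' [load_parameters()], so that a written parameter set round-trips to an
#' equal object.
#'
#' @param params A [gdm_params] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  yaml::write_yaml(params_to_config(params), path, precision = 15)
  invisible(path)
}
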
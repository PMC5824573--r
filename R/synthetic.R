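#' Cohort specification for the synthetic discharge-record generator
#'
#' Bundles the generating parameters of a synthetic mother/infant discharge
#' cohort. Length of stay is generated as `1 + NegBinomial(mu = mean_los - 1,
#' size)`, a discrete distribution truncated at one day whose mean is exactly
#' `mean_los` and whose right tail (controlled by `size`, smaller = heavier)
#' exercises the 99th-percentile outlier filter of the extraction.
#'
#' @param n_mothers Number of mothers.
#' @param gdm_prevalence Proportion of GDM pregnancies.
#' @param delivery_probs Tibble `group`, `drg`, `prob`; six-category vector
#'   per group, each summing to one.
#' @param los Tibble `group`, `drg`, `mean_los`, `size`.
#' @param tariffs Named numeric vector of DRG tariffs (EUR).
#' @param lookback_flag_fraction Proportion of GDM mothers whose 648.8 code
#'   appears only on a prior admission within the look-back window, not on
#'   the birth record.
#' @param missing_id_fraction Proportion of mothers without a patient ID
#'   (default 0.091); these lose look-back flaggability.
#' @param nondelivery_fraction Childbirth admissions with a non-delivery DRG
#'   code, as a fraction of `n_mothers` (they are excluded by
#'   [identify_deliveries()]).
#' @param n_infants Number of infant birth admissions.
#' @param complications Tibble `outcome`, `codes` (semicolon-separated ICD9),
#'   `rate`, `mean_cost`; complications are mutually exclusive, mirroring the
#'   exclusive outcome categories of the cost model.
#' @param normal_infant_cost Mean tariff of a complication-free infant
#'   admission (EUR).
#' @param cost_cv Coefficient of variation of the gamma tariff noise.
#' @param infant_missing_id_fraction Proportion of infant records without an
#'   ID.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A validated `gdm_cohort_spec` object.
#' @seealso [calibrated_cohort_spec()] for the packaged base-case spec.
#' @export
cohort_spec <- function(n_mothers,
                        gdm_prevalence = 0.109,
                        delivery_probs,
                        los,
                        tariffs,
                        lookback_flag_fraction = 0.15,
                        missing_id_fraction = 0.091,
                        nondelivery_fraction = 0.0083,
                        n_infants = n_mothers,
                        complications = NULL,
                        normal_infant_cost = 560,
                        cost_cv = 0.2,
                        infant_missing_id_fraction = 1 / 3,
                        seed = 1L) {
  spec <- structure(
    list(
      n_mothers = as.integer(n_mothers), gdm_prevalence = gdm_prevalence,
      delivery_probs = delivery_probs, los = los, tariffs = tariffs,
      lookback_flag_fraction = lookback_flag_fraction,
      missing_id_fraction = missing_id_fraction,
      nondelivery_fraction = nondelivery_fraction,
      n_infants = as.integer(n_infants), complications = complications,
      normal_infant_cost = normal_infant_cost, cost_cv = cost_cv,
      infant_missing_id_fraction = infant_missing_id_fraction,
      seed = as.integer(seed)
    ),
    class = "gdm_cohort_spec"
  )
  v <- validate_cohort_spec(spec)
  if (length(v)) abort(c("invalid cohort spec", setNames(v, rep("x", length(v)))))
  spec
}

#' Validate a cohort specification
#'
#' @param spec A `gdm_cohort_spec`.
#' @return Character vector of violations (empty when valid).
#' @export
validate_cohort_spec <- function(spec) {
  v <- character()
  say <- function(...) v <<- c(v, sprintf(...))
  if (spec$n_mothers <= 0) say("n_mothers must be > 0")
  for (f in c(
    "gdm_prevalence", "lookback_flag_fraction", "missing_id_fraction",
    "nondelivery_fraction", "infant_missing_id_fraction"
  )) {
    if (spec[[f]] < 0 || spec[[f]] > 1) say("%s outside [0,1]", f)
  }
  s <- spec$delivery_probs |>
    group_by(.data$group) |>
    summarise(s = sum(.data$prob), .groups = "drop")
  bad <- abs(s$s - 1) > 1e-9
  if (any(bad)) say("delivery_probs for group '%s' sum to %.6f, not 1", s$group[bad], s$s[bad])
  if (any(spec$delivery_probs$prob < 0)) say("delivery_probs must be >= 0")
  if (any(spec$los$mean_los < 1)) say("los mean_los must be >= 1 day")
  if (any(spec$los$size <= 0)) say("los size must be > 0")
  if (!all(.drg_codes %in% names(spec$tariffs))) say("tariffs must name all DRG codes 370-375")
  if (any(spec$tariffs <= 0)) say("tariffs must be > 0")
  if (!is.null(spec$complications)) {
    if (any(spec$complications$rate < 0) || sum(spec$complications$rate) > 1) {
      say("complication rates must be >= 0 and sum to <= 1")
    }
    if (any(spec$complications$mean_cost <= 0)) say("complication mean_cost must be > 0")
  }
  v
}

# shifted negative binomial LOS pmf and truncated mean
los_pmf <- function(k, mean_los, size) dnbinom(k - 1, size = size, mu = mean_los - 1)

truncated_mean <- function(threshold, mean_los, size) {
  k <- seq_len(threshold)
  p <- los_pmf(k, mean_los, size)
  sum(k * p) / sum(p)
}

# nearest-rank population percentile of a two-component LOS mixture
mixture_threshold <- function(w_gdm, mean_e, mean_g, size, q, k_max = 2000) {
  k <- seq_len(k_max)
  cdf <- cumsum((1 - w_gdm) * los_pmf(k, mean_e, size) + w_gdm * los_pmf(k, mean_g, size))
  which(cdf >= q)[[1]]
}

#' Calibrated base-case cohort specification
#'
#' Builds a cohort spec whose generating parameters reproduce the packaged
#' model inputs in expectation when the cohort is pushed through the
#' extraction pipeline:
#'
#' * delivery-category probabilities are the count ratios of
#'   [default_parameters()];
#' * for each DRG category, the GDM mean length of stay is solved
#'   (numerically) so that, after the 99th-percentile outlier truncation the
#'   extraction applies, the GDM-to-euglycemia LOS ratio equals the
#'   corresponding cost ratio, and the tariff is set so the LOS-adjusted
#'   costs equal the packaged per-category delivery costs;
#' * neonatal complication rates are the model-implied marginal outcome
#'   probabilities (mixing groups at the GDM prevalence), with mean tariffs
#'   equal to the packaged outcome costs.
#'
#' @param n_mothers Number of mothers (default 1e5).
#' @param seed Integer seed.
#' @param params Parameter set to calibrate against.
#' @param eug_mean_los Named vector of euglycemic mean LOS per DRG (days).
#' @param size Negative-binomial dispersion of the LOS distribution.
#' @param outlier_quantile The truncation quantile the extraction will use.
#' @inheritParams cohort_spec
#' @return A `gdm_cohort_spec`.
#' @export
calibrated_cohort_spec <- function(n_mothers = 1e5, seed = 1L,
                                   params = default_parameters(),
                                   eug_mean_los = c(
                                     "370" = 7, "371" = 4.5, "372" = 5,
                                     "373" = 3, "374" = 4, "375" = 6
                                   ),
                                   size = 10,
                                   outlier_quantile = 0.99,
                                   lookback_flag_fraction = 0.15,
                                   missing_id_fraction = 0.091) {
  d <- params$delivery
  prev <- params$population$gdm_prevalence
  probs <- d |> select("group", "drg", "prob")
  los_rows <- list()
  tariffs <- numeric()
  for (code in .drg_codes) {
    cost_e <- d$cost[d$drg == code & d$group == "euglycemia"]
    cost_g <- d$cost[d$drg == code & d$group == "gdm"]
    p_e <- d$prob[d$drg == code & d$group == "euglycemia"]
    p_g <- d$prob[d$drg == code & d$group == "gdm"]
    w_gdm <- prev * p_g / (prev * p_g + (1 - prev) * p_e)
    m_e <- unname(eug_mean_los[[code]])
    ratio <- cost_g / cost_e
    # GDM mean LOS such that the post-truncation LOS ratio matches the
    # cost ratio the extraction should reproduce
    objective <- function(m_g) {
      t <- mixture_threshold(w_gdm, m_e, m_g, size, outlier_quantile)
      truncated_mean(t, m_g, size) / truncated_mean(t, m_e, size) - ratio
    }
    m_g <- uniroot(objective, interval = c(m_e, m_e * (ratio + 0.5)), tol = 1e-8)$root
    t <- mixture_threshold(w_gdm, m_e, m_g, size, outlier_quantile)
    tm_e <- truncated_mean(t, m_e, size)
    tm_g <- truncated_mean(t, m_g, size)
    tm_mix <- (1 - w_gdm) * tm_e * sum(los_pmf(seq_len(t), m_e, size)) +
      w_gdm * tm_g * sum(los_pmf(seq_len(t), m_g, size))
    tm_mix <- tm_mix /
      ((1 - w_gdm) * sum(los_pmf(seq_len(t), m_e, size)) +
        w_gdm * sum(los_pmf(seq_len(t), m_g, size)))
    tariffs[[code]] <- cost_e * tm_mix / tm_e
    los_rows[[code]] <- tibble(
      group = .groups2, drg = code, mean_los = c(m_e, m_g), size = size
    )
  }
  # model-implied marginal complication rates at the population mix
  rates <- vapply(
    setdiff(.outcomes, "normal_newborn"),
    function(o) {
      sum(vapply(.groups2, function(g) {
        pm <- params$macrosomia$prob[params$macrosomia$group == g]
        oo <- params$outcomes
        p_m <- oo$prob[oo$outcome == o & oo$group == g & oo$macrosomia]
        p_n <- oo$prob[oo$outcome == o & oo$group == g & !oo$macrosomia]
        w <- if (g == "gdm") prev else 1 - prev
        w * (pm * p_m + (1 - pm) * p_n)
      }, numeric(1)))
    },
    numeric(1)
  )
  code_map <- default_complication_codes()
  complications <- tibble(
    outcome = names(rates),
    codes = vapply(code_map[names(rates)], paste, character(1), collapse = ";"),
    rate = unname(rates),
    mean_cost = params$outcome_costs$cost[
      match(names(rates), params$outcome_costs$outcome)
    ]
  )
  cohort_spec(
    n_mothers = n_mothers,
    gdm_prevalence = prev,
    delivery_probs = probs,
    los = bind_rows(los_rows),
    tariffs = tariffs,
    lookback_flag_fraction = lookback_flag_fraction,
    missing_id_fraction = missing_id_fraction,
    complications = complications,
    normal_infant_cost = params$outcome_costs$cost[
      params$outcome_costs$outcome == "normal_newborn"
    ],
    seed = seed
  )
}

#' Generate synthetic mother discharge records
#'
#' Draws one delivery admission per mother: GDM status (Bernoulli at the
#' spec prevalence), a DRG category (per-group multinomial), a length of
#' stay (shifted negative binomial) and the category tariff. GDM mothers
#' either carry code 648.8 on the birth record or — for the look-back
#' fraction — on a separate prior admission within 90 days of delivery; a
#' fraction of mothers have no patient ID and therefore cannot be linked.
#' A further set of childbirth admissions with non-delivery DRG codes is
#' appended, mimicking deliveries coded outside DRG 370-375.
#'
#' @param spec A `gdm_cohort_spec`.
#' @return A [discharge_records] tibble with a logical attribute-free extra
#'   column `true_gdm` on delivery rows (NA on auxiliary rows), so parameter
#'   recovery can be scored against the generating truth.
#' @export
generate_mothers <- function(spec) {
  v <- validate_cohort_spec(spec)
  if (length(v)) abort(c("invalid cohort spec", setNames(v, rep("x", length(v)))))
  withr::with_seed(spec$seed, {
    n <- spec$n_mothers
    gdm <- runif(n) < spec$gdm_prevalence
    group <- ifelse(gdm, "gdm", "euglycemia")
    drg <- character(n)
    for (g in .groups2) {
      pg <- spec$delivery_probs[spec$delivery_probs$group == g, ]
      idx <- group == g
      drg[idx] <- sample(pg$drg, sum(idx), replace = TRUE, prob = pg$prob)
    }
    key <- paste(group, drg)
    los_key <- paste(spec$los$group, spec$los$drg)
    mu <- spec$los$mean_los[match(key, los_key)]
    sz <- spec$los$size[match(key, los_key)]
    los <- 1 + rnbinom(n, size = sz, mu = mu - 1)
    day <- sample(181:545, n, replace = TRUE)
    patient_id <- sprintf("M%07d", seq_len(n))
    patient_id[runif(n) < spec$missing_id_fraction] <- NA_character_
    lookback_only <- gdm & runif(n) < spec$lookback_flag_fraction
    icd9 <- ifelse(gdm & !lookback_only, "648.8;V27.0", "V27.0")
    deliveries <- tibble(
      admission_id = sprintf("D%07d", seq_len(n)),
      patient_id = patient_id, role = "mother", drg = drg, icd9 = icd9,
      los_days = as.numeric(los), admission_day = as.numeric(day),
      tariff = unname(spec$tariffs[drg]), true_gdm = gdm
    )
    m <- sum(lookback_only)
    priors <- tibble(
      admission_id = sprintf("L%07d", seq_len(m)),
      patient_id = patient_id[lookback_only], role = "mother", drg = "467",
      icd9 = "648.8",
      los_days = as.numeric(1 + rpois(m, 1)),
      admission_day = as.numeric(day[lookback_only] - sample(1:90, m, replace = TRUE)),
      tariff = 300, true_gdm = NA
    )
    k <- round_half_up(n * spec$nondelivery_fraction)
    other <- tibble(
      admission_id = sprintf("X%07d", seq_len(k)),
      patient_id = sprintf("N%07d", seq_len(k)), role = "mother", drg = "468",
      icd9 = "650",
      los_days = as.numeric(1 + rpois(k, 4)),
      admission_day = as.numeric(sample(181:545, k, replace = TRUE)),
      tariff = 3000, true_gdm = NA
    )
    bind_rows(deliveries, priors, other)
  })
}

#' Generate synthetic infant discharge records
#'
#' Draws one birth admission per infant. Complications are mutually
#' exclusive (multinomial at the spec rates, mirroring the exclusive outcome
#' categories of the cost model); an affected infant carries one ICD9 code of
#' its complication and a gamma-distributed tariff centred on the
#' complication's mean cost, a healthy infant carries a generic newborn code
#' and a tariff centred on the normal-newborn cost. Infants are never linked
#' to mothers.
#'
#' @param spec A `gdm_cohort_spec` with a non-null `complications` table.
#' @return A [discharge_records] tibble.
#' @export
generate_infants <- function(spec) {
  v <- validate_cohort_spec(spec)
  if (length(v)) abort(c("invalid cohort spec", setNames(v, rep("x", length(v)))))
  withr::with_seed(spec$seed + 1L, {
    n <- spec$n_infants
    comp <- spec$complications
    if (is.null(comp)) comp <- tibble(outcome = character(), codes = character(), rate = numeric(), mean_cost = numeric())
    labels <- c(comp$outcome, "none")
    probs <- c(comp$rate, 1 - sum(comp$rate))
    outcome <- sample(labels, n, replace = TRUE, prob = probs)
    code_of <- function(o) {
      opts <- strsplit(comp$codes[comp$outcome == o], ";", fixed = TRUE)[[1]]
      sample(opts, 1)
    }
    icd9 <- vapply(outcome, function(o) {
      if (o == "none") "V30.0" else paste(code_of(o), "V30.0", sep = ";")
    }, character(1), USE.NAMES = FALSE)
    mean_cost <- ifelse(
      outcome == "none",
      spec$normal_infant_cost,
      comp$mean_cost[match(outcome, comp$outcome)]
    )
    tariff <- rgamma(
      n,
      shape = 1 / spec$cost_cv^2, scale = mean_cost * spec$cost_cv^2
    )
    patient_id <- sprintf("I%07d", seq_len(n))
    patient_id[runif(n) < spec$infant_missing_id_fraction] <- NA_character_
    tibble(
      admission_id = sprintf("B%07d", seq_len(n)),
      patient_id = patient_id, role = "infant", drg = "391", icd9 = icd9,
      los_days = as.numeric(1 + rpois(n, 2)),
      admission_day = as.numeric(sample(181:545, n, replace = TRUE)),
      tariff = tariff
    )
  })
}
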
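#' Vocabulary of one-way sensitivity parameters
#'
#' Lists every quantity that [one_way()] can perturb, with a structured id:
#'
#' * `cost_delivery:<drg>:<group>` — a delivery-category cost for one group;
#' * `cost_outcome:<outcome>` — a (group-independent) neonatal outcome cost;
#' * `prob_outcome:<outcome>:<group>:<macrosomia|no_macrosomia>` — a
#'   conditional neonatal outcome probability (the normal-newborn complement
#'   absorbs the change);
#' * `prob_macrosomia:<group>` — a macrosomia probability.
#'
#' @param params A [gdm_params] object.
#' @return A tibble with columns `id`, `kind` (`cost` / `probability`),
#'   `label`.
#' @export
dsa_parameters <- function(params) {
  d <- params$delivery
  del <- tibble(
    id = paste("cost_delivery", d$drg, d$group, sep = ":"),
    kind = "cost",
    label = paste0(d$description, " cost (", d$group, ")")
  )
  oc <- params$outcome_costs
  out_c <- tibble(
    id = paste0("cost_outcome:", oc$outcome),
    kind = "cost",
    label = paste0(oc$outcome, " cost")
  )
  o <- params$outcomes[params$outcomes$outcome != "normal_newborn", ]
  out_p <- tibble(
    id = paste(
      "prob_outcome", o$outcome, o$group,
      ifelse(o$macrosomia, "macrosomia", "no_macrosomia"),
      sep = ":"
    ),
    kind = "probability",
    label = paste0(
      o$outcome, " probability (", o$group, ", ",
      ifelse(o$macrosomia, "macrosomia", "no macrosomia"), ")"
    )
  )
  mac <- tibble(
    id = paste0("prob_macrosomia:", params$macrosomia$group),
    kind = "probability",
    label = paste0("macrosomia probability (", params$macrosomia$group, ")")
  )
  bind_rows(del, out_c, out_p, mac)
}

# apply a relative change to one named quantity, returning modified params
perturb_parameter <- function(params, parameter_id, rel_change) {
  valid <- dsa_parameters(params)$id
  if (!parameter_id %in% valid) {
    abort(c(
      sprintf("unknown sensitivity parameter id '%s'", parameter_id),
      i = paste("valid ids:", paste(valid, collapse = ", "))
    ))
  }
  parts <- strsplit(parameter_id, ":", fixed = TRUE)[[1]]
  f <- 1 + rel_change
  if (parts[[1]] == "cost_delivery") {
    i <- params$delivery$drg == parts[[2]] & params$delivery$group == parts[[3]]
    new <- params$delivery$cost[i] * f
    if (new <= 0) abort(sprintf("perturbed cost for '%s' is not positive", parameter_id))
    params$delivery$cost[i] <- new
  } else if (parts[[1]] == "cost_outcome") {
    i <- params$outcome_costs$outcome == parts[[2]]
    new <- params$outcome_costs$cost[i] * f
    if (new <= 0) abort(sprintf("perturbed cost for '%s' is not positive", parameter_id))
    params$outcome_costs$cost[i] <- new
  } else if (parts[[1]] == "prob_outcome") {
    macro <- parts[[4]] == "macrosomia"
    i <- params$outcomes$outcome == parts[[2]] &
      params$outcomes$group == parts[[3]] & params$outcomes$macrosomia == macro
    new <- params$outcomes$prob[i] * f
    if (new < 0 || new > 1) {
      abort(sprintf("perturbed probability for '%s' is outside [0, 1]", parameter_id))
    }
    params$outcomes$prob[i] <- new
    # the normal-newborn complement absorbs the change within the branch
    j <- params$outcomes$outcome == "normal_newborn" &
      params$outcomes$group == parts[[3]] & params$outcomes$macrosomia == macro
    k <- params$outcomes$group == parts[[3]] & params$outcomes$macrosomia == macro &
      params$outcomes$outcome != "normal_newborn"
    normal <- 1 - sum(params$outcomes$prob[k])
    if (normal < 0) {
      abort(sprintf(
        "perturbing '%s' drives the normal-newborn probability below 0", parameter_id
      ))
    }
    params$outcomes$prob[j] <- normal
  } else { # prob_macrosomia
    i <- params$macrosomia$group == parts[[2]]
    new <- params$macrosomia$prob[i] * f
    if (new < 0 || new > 1) {
      abort(sprintf("perturbed probability for '%s' is outside [0, 1]", parameter_id))
    }
    params$macrosomia$prob[i] <- new
  }
  params
}

inpatient_cost <- function(params, group) {
  mother_inpatient_cost(params, group) + infant_inpatient_cost(params, group)
}

#' One-way deterministic sensitivity analysis
#'
#' Multiplies one model quantity by `1 + rel_change` and recomputes the
#' inpatient (mother plus infant) cost per case in both groups. When a
#' conditional neonatal outcome probability is perturbed, the normal-newborn
#' probability absorbs the complement so the branch still sums to one.
#' Outpatient costs are outside the scope of the sensitivity analyses and are
#' not included in the reported cost columns.
#'
#' @param params A [gdm_params] object.
#' @param parameter_id One id from [dsa_parameters()].
#' @param rel_change Relative change, e.g. `-0.2` or `0.2`.
#' @return A one-row tibble: `parameter_id`, `rel_change`,
#'   `cost_euglycemia`, `cost_gdm`, `delta` (all EUR, inpatient per case).
#' @examples
#' one_way(default_parameters(), "cost_delivery:371:gdm", -0.2)
#' @export
one_way <- function(params, parameter_id, rel_change) {
  p <- perturb_parameter(params, parameter_id, rel_change)
  e <- inpatient_cost(p, "euglycemia")
  g <- inpatient_cost(p, "gdm")
  tibble(
    parameter_id = parameter_id, rel_change = rel_change,
    cost_euglycemia = e, cost_gdm = g, delta = g - e
  )
}

#' Tornado analysis
#'
#' Runs [one_way()] at `-rel_change` and `+rel_change` for each parameter and
#' ranks parameters by the width of the induced range of the GDM minus
#' euglycemia inpatient cost difference.
#'
#' @param params A [gdm_params] object.
#' @param parameter_ids Ids from [dsa_parameters()]; defaults to all of them.
#' @param rel_change Half-width of the relative variation (default 0.2).
#' @return A tibble of class `gdm_dsa`, two rows per parameter (both
#'   directions), sorted by decreasing `delta_range`; the base-case costs are
#'   stored in the `base` attribute.
#' @examples
#' tornado(default_parameters(), c("cost_delivery:371:gdm", "cost_outcome:hypoglycemia"))
#' @export
tornado <- function(params, parameter_ids = dsa_parameters(params)$id, rel_change = 0.2) {
  rows <- purrr::map(parameter_ids, function(id) {
    bind_rows(
      one_way(params, id, -abs(rel_change)),
      one_way(params, id, +abs(rel_change))
    )
  })
  x <- bind_rows(rows)
  if (nrow(x)) {
    x <- x |>
      group_by(.data$parameter_id) |>
      mutate(delta_range = abs(diff(range(.data$delta)))) |>
      ungroup() |>
      arrange(desc(.data$delta_range), .data$parameter_id, .data$rel_change)
  } else {
    x$delta_range <- numeric()
  }
  attr(x, "base") <- c(
    cost_euglycemia = inpatient_cost(params, "euglycemia"),
    cost_gdm = inpatient_cost(params, "gdm")
  )
  class(x) <- c("gdm_dsa", class(x))
  x
}

# ---- distribution helpers ---------------------------------------------------

#' Beta distribution parameters from counts
#'
#' Parameterises a beta distribution directly from event counts: shape
#' parameters `(successes, total - successes)`, so the mean is
#' `successes / total`. Degenerate inputs (`successes` 0 or `total`) yield a
#' shape of zero and are sampled as a point mass at 0 or 1.
#'
#' @param successes,total Non-negative counts, `successes <= total`,
#'   `total > 0`.
#' @return A list with `shape1`, `shape2` and the implied `mean`.
#' @examples
#' beta_from_counts(4019, 11434)$mean
#' @export
beta_from_counts <- function(successes, total) {
  if (total <= 0) abort("total must be > 0")
  if (successes < 0 || successes > total) abort("successes must be in [0, total]")
  list(shape1 = successes, shape2 = total - successes, mean = successes / total)
}

#' Gamma distribution parameters from a mean and coefficient of variation
#'
#' Moment-matching parameterisation: `shape = 1 / cv^2`,
#' `scale = mean * cv^2`, so the distribution has the requested mean and
#' coefficient of variation.
#'
#' @param mean Target mean (> 0).
#' @param cv Target coefficient of variation (> 0).
#' @return A list with `shape` and `scale`.
#' @examples
#' gamma_from_moments(560, 0.2)
#' @export
gamma_from_moments <- function(mean, cv) {
  if (mean <= 0) abort("mean must be > 0")
  if (cv <= 0) abort("cv must be > 0")
  list(shape = 1 / cv^2, scale = mean * cv^2)
}

# n draws from Dirichlet(alpha); zero alphas give exact zero components
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(0, n, k)
  pos <- alpha > 0
  x[, pos] <- matrix(
    rgamma(n * sum(pos), shape = rep(alpha[pos], each = n)),
    n, sum(pos)
  )
  x / rowSums(x)
}

# moment-matched beta draws with mean p and sd cv * p; point mass at 0 or 1
rbeta_mm <- function(n, p, cv) {
  if (p <= 0 || p >= 1) {
    return(rep(max(0, min(1, p)), n))
  }
  s <- (1 - p) / (cv^2 * p) - 1
  if (s <= 0) {
    abort(sprintf("cv %.3f too large for a beta with mean %.4f", cv, p))
  }
  rbeta(n, shape1 = p * s, shape2 = (1 - p) * s)
}

rgamma_mm <- function(n, mean, cv) {
  g <- gamma_from_moments(mean, cv)
  rgamma(n, shape = g$shape, scale = g$scale)
}

# Dirichlet concentration for a point-probability vector: moment-matched so
# that the largest non-reference component has coefficient of variation cv
# (the smaller components then have wider relative uncertainty, which is the
# conservative direction). The reference component — the by-difference
# normal-newborn complement — is excluded from the matching.
dirichlet_concentration <- function(p, cv, exclude = NULL) {
  q <- if (is.null(exclude)) p else p[-exclude]
  pmax_ <- max(q)
  s <- (1 - pmax_) / (cv^2 * pmax_) - 1
  if (s <= 0) abort(sprintf("cv %.3f too large for a Dirichlet with max component %.4f", cv, pmax_))
  s
}

# ---- probabilistic sensitivity analysis ------------------------------------

#' Monte Carlo probabilistic sensitivity analysis
#'
#' Draws every model probability and inpatient cost from an uncertainty
#' distribution and recomputes the inpatient (mother plus infant) cost per
#' case for both groups at each iteration. Probabilities are beta/Dirichlet
#' distributed and costs gamma distributed (moment-matched, coefficient of
#' variation `cost_cv`).
#'
#' With `probability_source = "counts"` (default) each delivery-mix vector is
#' drawn jointly from a Dirichlet distribution whose concentrations are the
#' observed admission counts (each marginal is then beta), preserving the
#' sum-to-one constraint; neonatal outcome vectors, for which only point
#' probabilities are available, are drawn from a Dirichlet moment-matched at
#' relative spread `prob_cv`. With `"moments"` every probability is an
#' independent moment-matched beta draw and each vector is renormalised.
#' Macrosomia probabilities are always moment-matched betas.
#'
#' Draws are vectorised in a fixed order (delivery probabilities per group,
#' delivery costs per group, macrosomia, outcome vectors per group and
#' macrosomia status, outcome costs), so results are reproducible for a given
#' `seed`.
#'
#' @param params A [gdm_params] object.
#' @param n_iterations Number of Monte Carlo iterations (default 1000).
#' @param seed Integer seed for the random number generator.
#' @param cost_cv Coefficient of variation of all cost distributions
#'   (default 0.2).
#' @param prob_cv Relative spread used to moment-match probability
#'   distributions that have no underlying counts (default 0.2).
#' @param probability_source `"counts"` or `"moments"`, see Details.
#' @return An object of class `gdm_psa`: a list with `draws` (tibble
#'   `iteration`, `euglycemia`, `gdm`, `delta`), the base-case values and the
#'   configuration. Use [tidy()] / [glance()] for summaries and [autoplot()]
#'   for the draw histograms.
#' @examples
#' psa <- run_psa(default_parameters(), n_iterations = 200, seed = 1)
#' tidy(psa)
#' @export
run_psa <- function(params, n_iterations = 1000, seed = 1L, cost_cv = 0.2,
                    prob_cv = 0.2, probability_source = c("counts", "moments")) {
  probability_source <- match.arg(probability_source)
  if (n_iterations <= 0) abort("n_iterations must be > 0")
  if (cost_cv <= 0) abort("cost_cv must be > 0")
  stop_if_invalid(params)
  n <- as.integer(n_iterations)
  set.seed(seed)

  draw_simplex <- function(probs, counts, exclude = NULL) {
    if (probability_source == "counts" && all(!is.na(counts))) {
      rdirichlet(n, counts)
    } else if (probability_source == "counts") {
      rdirichlet(n, probs * dirichlet_concentration(probs, prob_cv, exclude))
    } else {
      x <- vapply(probs, function(p) rbeta_mm(n, p, prob_cv), numeric(n))
      x / rowSums(x)
    }
  }

  mother_draws <- function(g) {
    d <- params$delivery[params$delivery$group == g, ]
    p_del <- draw_simplex(d$prob, d$count)
    c_del <- vapply(d$cost, function(m) rgamma_mm(n, m, cost_cv), numeric(n))
    rowSums(p_del * c_del)
  }
  outcome_vectors <- function(g) {
    br <- params$outcomes[params$outcomes$group == g, ]
    lapply(c(TRUE, FALSE), function(macro) {
      rows <- br[br$macrosomia == macro, ]
      draw_simplex(
        rows$prob[match(.outcomes, rows$outcome)],
        rep(NA_real_, length(.outcomes)),
        exclude = which(.outcomes == "normal_newborn")
      )
    })
  }

  mother <- lapply(setNames(.groups2, .groups2), mother_draws)
  pm <- lapply(setNames(.groups2, .groups2), function(g) {
    rbeta_mm(n, params$macrosomia$prob[params$macrosomia$group == g], prob_cv)
  })
  vecs <- lapply(setNames(.groups2, .groups2), outcome_vectors)
  # neonatal outcome costs are group-independent: one shared draw per outcome
  oc <- params$outcome_costs$cost[match(.outcomes, params$outcome_costs$outcome)]
  c_out <- vapply(oc, function(m) rgamma_mm(n, m, cost_cv), numeric(n))

  total <- function(g) {
    infant <- pm[[g]] * rowSums(vecs[[g]][[1]] * c_out) +
      (1 - pm[[g]]) * rowSums(vecs[[g]][[2]] * c_out)
    mother[[g]] + infant
  }
  eug <- total("euglycemia")
  gdm <- total("gdm")
  structure(
    list(
      draws = tibble(
        iteration = seq_len(n), euglycemia = eug, gdm = gdm, delta = gdm - eug
      ),
      base = c(
        euglycemia = inpatient_cost(params, "euglycemia"),
        gdm = inpatient_cost(params, "gdm")
      ),
      n_iterations = n, seed = seed, cost_cv = cost_cv, prob_cv = prob_cv,
      probability_source = probability_source
    ),
    class = "gdm_psa"
  )
}

#' @export
print.gdm_psa <- function(x, ...) {
  cat(sprintf(
    "<gdm_psa> %d iterations (seed %s, cost cv %.2f, probabilities from %s)\n",
    x$n_iterations, format(x$seed), x$cost_cv, x$probability_source
  ))
  print(tidy(x))
  invisible(x)
}
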
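test_that("a zero perturbation reproduces the base case", {
  p <- default_parameters()
  base_e <- mother_inpatient_cost(p, "euglycemia") + infant_inpatient_cost(p, "euglycemia")
  base_g <- mother_inpatient_cost(p, "gdm") + infant_inpatient_cost(p, "gdm")
  for (id in c("cost_delivery:371:gdm", "cost_outcome:hypoglycemia",
               "prob_outcome:respiratory_distress:euglycemia:no_macrosomia")) {
    r <- one_way(p, id, 0)
    expect_equal(r$cost_euglycemia, base_e, tolerance = 1e-12)
    expect_equal(r$cost_gdm, base_g, tolerance = 1e-12)
  }
})

test_that("invalid perturbations are rejected with informative errors", {
  p <- default_parameters()
  expect_error(one_way(p, "cost_delivery:999:gdm", 0.2), "valid ids")
  expect_error(one_way(p, "prob_macrosomia:gdm", 15), "outside \\[0, 1\\]")
  # pushing a conditional probability so far up that the complement goes negative
  q <- p
  q$outcomes$prob[q$outcomes$outcome == "hyperbilirubinemia" &
    q$outcomes$group == "gdm" & !q$outcomes$macrosomia] <- 0.8
  normal <- q$outcomes$outcome == "normal_newborn" & q$outcomes$group == "gdm" &
    !q$outcomes$macrosomia
  others <- q$outcomes$group == "gdm" & !q$outcomes$macrosomia &
    q$outcomes$outcome != "normal_newborn"
  q$outcomes$prob[normal] <- 1 - sum(q$outcomes$prob[others])
  expect_error(
    one_way(q, "prob_outcome:hyperbilirubinemia:gdm:no_macrosomia", 0.2),
    "normal-newborn"
  )
})

test_that("varying a GDM-only parameter leaves the euglycemia column at base", {
  p <- default_parameters()
  base <- one_way(p, "cost_delivery:371:gdm", 0)
  r <- one_way(p, "cost_delivery:371:gdm", -0.2)
  expect_equal(r$cost_euglycemia, base$cost_euglycemia)
  expect_equal(r$delta, r$cost_gdm - r$cost_euglycemia, tolerance = 1e-9)
})

test_that("cost perturbations shift the group cost by rel_change x cost x exposure", {
  for (seed in 1:5) {
    p <- random_params(seed)
    base_g <- mother_inpatient_cost(p, "gdm") + infant_inpatient_cost(p, "gdm")
    # exposure weight of a delivery cost is its leaf probability
    leaves <- enumerate_tree(p, "gdm")
    d371 <- p$delivery[p$delivery$drg == "371" & p$delivery$group == "gdm", ]
    r <- one_way(p, "cost_delivery:371:gdm", 0.2)
    expect_equal(r$cost_gdm, base_g + 0.2 * d371$cost * d371$prob, tolerance = 1e-9)
    # exposure weight of an outcome cost spans both macrosomia branches
    w <- sum(leaves$probability[leaves$system == "infant" &
      grepl("hypoglycemia", leaves$label)])
    c0 <- p$outcome_costs$cost[p$outcome_costs$outcome == "hypoglycemia"]
    r <- one_way(p, "cost_outcome:hypoglycemia", -0.2)
    expect_equal(r$cost_gdm, base_g - 0.2 * c0 * w, tolerance = 1e-9)
  }
})

test_that("the tornado ranks parameters by induced delta range", {
  p <- default_parameters()
  ids <- c(
    "cost_delivery:371:gdm", "cost_outcome:hypoglycemia",
    "prob_outcome:hyperbilirubinemia:gdm:no_macrosomia"
  )
  t <- tornado(p, ids, 0.2)
  expect_equal(nrow(t), 6)
  s <- tidy(t)
  expect_equal(s$delta_range, sort(s$delta_range, decreasing = TRUE))
  expect_equal(s$parameter_id[[1]], "cost_delivery:371:gdm")
  expect_equal(nrow(tornado(p, "cost_outcome:hypoglycemia")), 2)
  expect_equal(nrow(tornado(p, character(0))), 0)
  g <- glance(t)
  expect_equal(g$top_parameter, "cost_delivery:371:gdm")
})

test_that("distribution parameterisations match their moments", {
  b <- beta_from_counts(4019, 11434)
  expect_equal(b$mean, 4019 / 11434)
  expect_equal(b$shape1 / (b$shape1 + b$shape2), 0.3515, tolerance = 1e-4)
  expect_equal(beta_from_counts(0, 10)$mean, 0)
  expect_equal(beta_from_counts(10, 10)$mean, 1)
  expect_error(beta_from_counts(1, 0), "total")

  g <- gamma_from_moments(560, 0.2)
  expect_equal(g$shape, 25)
  expect_equal(g$scale, 22.4)
  set.seed(1)
  x <- rgamma(1e5, shape = g$shape, scale = g$scale)
  expect_equal(mean(x), 560, tolerance = 0.005)
  expect_equal(sd(x) / mean(x), 0.2, tolerance = 0.02)
  expect_error(gamma_from_moments(-5, 0.2), "mean")
  expect_error(gamma_from_moments(5, 0), "cv")
})

test_that("the PSA is seed-deterministic and respects its configuration", {
  p <- default_parameters()
  a <- run_psa(p, n_iterations = 300, seed = 42)
  b <- run_psa(p, n_iterations = 300, seed = 42)
  expect_identical(a$draws, b$draws)
  expect_equal(nrow(a$draws), 300)
  expect_false(identical(a$draws, run_psa(p, 300, seed = 43)$draws))

  s <- tidy(a)
  expect_true(all(s$min <= s$p10 & s$p10 <= s$median & s$median <= s$p90 & s$p90 <= s$max))

  # shrinking cost spread concentrates the draws around the base case
  tight <- run_psa(p, n_iterations = 300, seed = 42, cost_cv = 0.01, prob_cv = 0.01)
  st <- tidy(tight)
  expect_lt(
    st$sd[st$group == "euglycemia"],
    s$sd[s$group == "euglycemia"] / 5
  )
  expect_equal(
    st$mean[st$group == "euglycemia"], unname(a$base[["euglycemia"]]),
    tolerance = 0.01
  )

  # the independent-beta parameterisation is also available
  m <- run_psa(p, n_iterations = 300, seed = 42, probability_source = "moments")
  expect_equal(
    tidy(m)$mean[1], unname(a$base[["euglycemia"]]),
    tolerance = 0.05
  )
})
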
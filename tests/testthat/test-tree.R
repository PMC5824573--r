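test_that("degenerate branches collapse to the single leaf cost", {
  p <- default_parameters()
  # all delivery probability on one category
  p$delivery$count <- NA_real_
  p$delivery$prob <- rep(c(0, 1, 0, 0, 0, 0), each = 2)
  expect_equal(
    mother_inpatient_cost(p, "gdm"),
    p$delivery$cost[p$delivery$drg == "371" & p$delivery$group == "gdm"]
  )
  # every infant a normal newborn
  q <- default_parameters()
  q$outcomes$prob <- ifelse(q$outcomes$outcome == "normal_newborn", 1, 0)
  expect_equal(infant_inpatient_cost(q, "euglycemia"), 560)
})

test_that("exhaustive leaf enumeration agrees with the closed-form sums", {
  for (seed in 1:20) {
    p <- random_params(seed)
    for (g in c("euglycemia", "gdm")) {
      leaves <- enumerate_tree(p, g)
      expect_equal(nrow(leaves[leaves$system == "delivery", ]), 6)
      expect_equal(nrow(leaves[leaves$system == "infant", ]), 12)
      sums <- tapply(leaves$probability, leaves$system, sum)
      expect_true(all(abs(sums - 1) < 1e-9))
      ev <- sum(leaves$probability * leaves$cost)
      closed <- mother_inpatient_cost(p, g) + infant_inpatient_cost(p, g)
      expect_equal(ev, closed, tolerance = 1e-9)
      # each branch system's expectation lies within its leaf cost range
      for (s in c("delivery", "infant")) {
        l <- leaves[leaves$system == s, ]
        expect_gte(sum(l$probability * l$cost), min(l$cost) - 1e-9)
        expect_lte(sum(l$probability * l$cost), max(l$cost) + 1e-9)
      }
    }
  }
})

test_that("a delivery leaf probability is the joint branch product", {
  leaves <- enumerate_tree(default_parameters(), "euglycemia")
  rds <- leaves[leaves$label == "macrosomia / respiratory_distress", ]
  expect_equal(rds$probability, 0.074 * 0.017)
})

test_that("cost per case is affine in costs", {
  p <- default_parameters()
  base <- cost_per_case(p)
  doubled <- p
  doubled$delivery$cost <- doubled$delivery$cost * 2
  doubled$outcome_costs$cost <- doubled$outcome_costs$cost * 2
  doubled$resources$unit_cost <- doubled$resources$unit_cost * 2
  b2 <- cost_per_case(doubled)
  expect_equal(b2$total, base$total * 2, tolerance = 1e-12)
  expect_equal(b2$inpatient_total, base$inpatient_total * 2, tolerance = 1e-12)
})

test_that("breakdown components and deltas are coherent", {
  b <- cost_per_case(default_parameters())
  expect_equal(
    b$total, b$outpatient + b$mother_inpatient + b$infant_inpatient,
    tolerance = 1e-9
  )
  for (col in c("outpatient", "mother_inpatient", "infant_inpatient", "total")) {
    expect_equal(
      b[[col]][b$group == "delta"],
      b[[col]][b$group == "gdm"] - b[[col]][b$group == "euglycemia"],
      tolerance = 1e-9
    )
  }
})

test_that("with GDM set equal to euglycemia, only the screening pathway differs", {
  p <- default_parameters()
  for (col in c("count", "prob", "cost")) {
    p$delivery[[col]][p$delivery$group == "gdm"] <-
      p$delivery[[col]][p$delivery$group == "euglycemia"]
  }
  p$macrosomia$prob[2] <- p$macrosomia$prob[1]
  eug <- p$outcomes[p$outcomes$group == "euglycemia", ]
  p$outcomes$prob[p$outcomes$group == "gdm"] <-
    eug$prob[match(
      paste(
        p$outcomes$outcome[p$outcomes$group == "gdm"],
        p$outcomes$macrosomia[p$outcomes$group == "gdm"]
      ),
      paste(eug$outcome, eug$macrosomia)
    )]
  p$population$insulin_share <- 0
  b <- cost_per_case(p)
  out <- outpatient_totals(p)
  expect_equal(b$inpatient_total[b$group == "delta"], 0, tolerance = 1e-9)
  expect_equal(
    b$total[b$group == "delta"],
    out$total[out$group == "gdm_diet"] - out$total[out$group == "euglycemia"],
    tolerance = 1e-9
  )
})

test_that("the national burden scales cases by the per-case difference", {
  p <- default_parameters()
  b <- national_burden(p)
  expect_equal(b$gdm_cases, round(p$population$births * p$population$gdm_prevalence))
  bd <- cost_per_case(p)
  expect_equal(b$incremental_cost, b$gdm_cases * bd$total[bd$group == "delta"])

  p$population$gdm_prevalence <- 0
  b0 <- national_burden(p)
  expect_equal(b0$gdm_cases, 0)
  expect_equal(b0$incremental_cost, 0)
})
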
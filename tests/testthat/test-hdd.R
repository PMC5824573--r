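test_that("delivery identification filters on the DRG range", {
  recs <- dplyr::bind_rows(
    record("A1", drg = "370"), record("A2", drg = "373"), record("A3", drg = "375"),
    record("A4", drg = "468", icd9 = "650"), # childbirth coded outside the range
    record("A5", drg = "127"), # unrelated admission
    record("A6", drg = "391", role = "infant")
  )
  del <- identify_deliveries(recs)
  expect_equal(del$admission_id, c("A1", "A2", "A3"))
  expect_equal(attr(del, "n_excluded"), 1)
  empty <- identify_deliveries(recs[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("GDM flagging uses the birth record or a linked look-back admission", {
  recs <- dplyr::bind_rows(
    record("D1", patient_id = "P1", icd9 = "648.8;V27.0", admission_day = 300),
    record("D2", patient_id = "P2", admission_day = 300),
    record("P2a", patient_id = "P2", drg = "467", icd9 = "648.8", admission_day = 260),
    record("D3", patient_id = "P3", admission_day = 300),
    record("P3a", patient_id = "P3", drg = "467", icd9 = "648.8", admission_day = 180),
    record("D4", patient_id = NA, admission_day = 300),
    record("D5", patient_id = "P5", admission_day = 300)
  )
  del <- identify_deliveries(recs)
  flags <- flag_gdm(recs, del)
  got <- setNames(flags$gdm, flags$admission_id)
  expect_true(got[["D1"]]) # own code
  expect_true(got[["D2"]]) # prior admission 40 days earlier
  expect_false(got[["D3"]]) # prior admission 120 days earlier: outside window
  expect_false(got[["D4"]])
  expect_false(got[["D5"]])

  # boundary: exactly at the window edge is included, the delivery day is not
  edge <- dplyr::bind_rows(
    record("D6", patient_id = "P6", admission_day = 300),
    record("P6a", patient_id = "P6", drg = "467", icd9 = "648.8", admission_day = 210),
    record("D7", patient_id = "P7", admission_day = 300),
    record("P7a", patient_id = "P7", drg = "467", icd9 = "648.8", admission_day = 300)
  )
  f <- flag_gdm(edge, identify_deliveries(edge))
  expect_true(f$gdm[f$admission_id == "D6"])
  expect_false(f$gdm[f$admission_id == "D7"])
})

test_that("the delivery mix is the normalised per-group category count", {
  one <- record("D1", icd9 = "648.8", drg = "371")
  two <- record("D2", patient_id = "P2", drg = "373")
  del <- identify_deliveries(dplyr::bind_rows(one, two))
  mix <- estimate_delivery_mix(del, flag_gdm(dplyr::bind_rows(one, two), del))
  expect_equal(mix$prob[mix$drg == "371" & mix$group == "gdm"], 1)
  expect_equal(sum(mix$prob[mix$group == "gdm"]), 1)

  # published GDM counts reproduce the printed percentages
  counts <- c("370" = 538, "371" = 4019, "372" = 447, "373" = 6287, "374" = 125, "375" = 18)
  recs <- dplyr::bind_rows(purrr::imap(
    counts,
    function(k, drg) record(paste0(drg, "_", seq_len(k)), icd9 = "648.8", drg = drg)
  ))
  recs$admission_id <- sprintf("D%05d", seq_len(nrow(recs)))
  recs$patient_id <- sprintf("P%05d", seq_len(nrow(recs)))
  del <- identify_deliveries(recs)
  # all flagged GDM: add one euglycemic so both groups exist
  recs2 <- dplyr::bind_rows(recs, record("E1", patient_id = "E"))
  del <- identify_deliveries(recs2)
  mix <- estimate_delivery_mix(del, flag_gdm(recs2, del))
  gdm <- mix[mix$group == "gdm", ]
  expect_true(all(abs(100 * gdm$prob - c(4.7, 35.2, 3.9, 55.0, 1.1, 0.2)) <= 0.06))

  expect_error(
    estimate_delivery_mix(identify_deliveries(one), flag_gdm(one, identify_deliveries(one))),
    "zero deliveries"
  )
})

test_that("LOS-adjusted costing matches a hand computation", {
  # 20 admissions in one category: 12 euglycemic (LOS 2..4), 8 GDM (LOS 3..5)
  los_e <- c(2, 3, 4, 3, 2, 4, 3, 3, 2, 4, 3, 3)
  los_g <- c(4, 5, 3, 4, 5, 4, 3, 4)
  recs <- dplyr::bind_rows(
    record(sprintf("E%02d", 1:12), patient_id = sprintf("PE%02d", 1:12), los_days = los_e),
    record(sprintf("G%02d", 1:8), patient_id = sprintf("PG%02d", 1:8),
           icd9 = "648.8", los_days = los_g)
  )
  del <- identify_deliveries(recs)
  costs <- los_adjusted_cost(del, flag_gdm(recs, del), c("371" = 2000))
  daily <- 2000 / mean(c(los_e, los_g))
  expect_equal(costs$cost[costs$group == "euglycemia"], daily * mean(los_e))
  expect_equal(costs$cost[costs$group == "gdm"], daily * mean(los_g))
  expect_equal(costs$n_excluded, c(0L, 0L))

  # equal group means recover the tariff itself
  same <- dplyr::bind_rows(
    record("E1", los_days = 3), record("G1", patient_id = "X", icd9 = "648.8", los_days = 3)
  )
  del <- identify_deliveries(same)
  costs <- los_adjusted_cost(del, flag_gdm(same, del), c("371" = 2000))
  expect_equal(costs$cost, c(2000, 2000))
})

test_that("LOS outliers above the category 99th percentile are excluded", {
  set.seed(5)
  los <- c(rep(3, 197), 4, 4, 200) # nearest-rank 99th percentile is 4
  recs <- record(sprintf("D%03d", seq_along(los)),
    patient_id = sprintf("P%03d", seq_along(los)), los_days = los
  )
  recs$icd9[1:20] <- "648.8"
  del <- identify_deliveries(recs)
  costs <- los_adjusted_cost(del, flag_gdm(recs, del), c("371" = 2000))
  expect_equal(sum(costs$n_excluded), 1) # only the extreme stay; ties retained
  expect_equal(sum(costs$n_kept), 199)
  # never more than (1 - q + 1/n) of a category
  expect_lte(sum(costs$n_excluded) / length(los), 1 - 0.99 + 1 / length(los))
})

test_that("infant complication costs are pooled means over matching admissions", {
  recs <- dplyr::bind_rows(
    record("I1", role = "infant", icd9 = "769", tariff = 20000),
    record("I2", role = "infant", icd9 = "V30.0;769", tariff = 25000),
    record("I3", role = "infant", icd9 = "769;775.0", tariff = 28013.4),
    record("I4", role = "infant", icd9 = "775.6", tariff = 8000),
    record("I5", role = "infant", icd9 = "V30.0", tariff = 560)
  )
  ev <- infant_event_costs(recs)
  expect_equal(ev$mean_cost[ev$outcome == "respiratory_distress"], 24337.8)
  # the double-coded admission contributes to both outcome means
  expect_equal(ev$mean_cost[ev$outcome == "hypoglycemia"], mean(c(28013.4, 8000)))
  expect_equal(ev$n_admissions[ev$outcome == "hypoglycemia"], 2)
  # absent outcomes are missing, not zero
  expect_true(is.na(ev$mean_cost[ev$outcome == "shoulder_dystocia"]))
  expect_equal(ev$n_admissions[ev$outcome == "shoulder_dystocia"], 0)
})

test_that("extraction is a pure function of its input records", {
  spec <- calibrated_cohort_spec(n_mothers = 20000, seed = 99)
  m <- generate_mothers(spec)
  a <- extract_model_parameters(m, spec$tariffs)
  b <- extract_model_parameters(m, spec$tariffs)
  expect_equal(a, b)
})

test_that("discharge records round-trip through the CSV dialect", {
  recs <- dplyr::bind_rows(
    record("D1", icd9 = "648.8;V27.0"),
    record("D2", patient_id = NA)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_discharge_records(recs, path)
  back <- read_discharge_records(path)
  expect_equal(as.data.frame(back), as.data.frame(recs))
})
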
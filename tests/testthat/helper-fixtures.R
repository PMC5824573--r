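# one discharge-record row with defaults, for hand-built fixtures
record <- function(admission_id, patient_id = "P1", role = "mother",
                   drg = "371", icd9 = "", los_days = 3, admission_day = 200,
                   tariff = 2000) {
  tibble::tibble(
    admission_id = admission_id, patient_id = patient_id, role = role,
    drg = drg, icd9 = icd9, los_days = los_days,
    admission_day = admission_day, tariff = tariff
  )
}

# a randomised but structurally valid parameter set, for property tests
random_params <- function(seed) {
  set.seed(seed)
  p <- default_parameters()
  p$delivery$cost <- runif(nrow(p$delivery), 500, 5000)
  p$delivery$count <- NA_real_
  for (g in unique(p$delivery$group)) {
    idx <- p$delivery$group == g
    pr <- rgamma(sum(idx), shape = 1)
    p$delivery$prob[idx] <- pr / sum(pr)
  }
  p$macrosomia$prob <- runif(2, 0.01, 0.3)
  for (g in unique(p$outcomes$group)) {
    for (m in c(TRUE, FALSE)) {
      idx <- p$outcomes$group == g & p$outcomes$macrosomia == m
      named <- idx & p$outcomes$outcome != "normal_newborn"
      pr <- runif(sum(named), 0, 0.15)
      p$outcomes$prob[named] <- pr
      p$outcomes$prob[idx & p$outcomes$outcome == "normal_newborn"] <- 1 - sum(pr)
    }
  }
  p$outcome_costs$cost <- runif(nrow(p$outcome_costs), 100, 30000)
  stopifnot(length(validate_parameters(p)) == 0)
  p
}
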
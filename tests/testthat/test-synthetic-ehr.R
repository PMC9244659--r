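# Synthetic cohort generator: determinism, invariants, coupling, round trip.

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_patients = -1), "nonnegative")
  bad <- ardswatch:::.DEFAULT_PREVALENCE
  bad["ards_1"] <- 1.2
  expect_error(cohort_config(10, prevalence_targets = bad), "\\[0, 1\\]")
  infeasible <- ardswatch:::.DEFAULT_PREVALENCE
  infeasible["ards_1"] <- 0.2   # exceeds ards_5
  expect_error(cohort_config(10, prevalence_targets = infeasible), "nesting")
})

test_that("empty cohort and determinism contracts hold", {
  cfg0 <- cohort_config(n_patients = 0, seed = 7)
  expect_length(generate_cohort(cfg0), 0)

  cfg <- cohort_config(n_patients = 25, seed = 7)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  attr(c1, "config") <- attr(c2, "config") <- NULL
  expect_identical(c1, c2)

  c3 <- generate_cohort(cohort_config(n_patients = 25, seed = 8))
  attr(c3, "config") <- NULL
  expect_false(identical(c1, c3))

  cfgp <- cohort_config(n_patients = 5, seed = 1)
  r1 <- generate_patient(0.5, cfgp, stream_seed = 99)
  r2 <- generate_patient(0.5, cfgp, stream_seed = 99)
  expect_identical(r1, r2)
})

test_that("severity limits behave deterministically", {
  cfg <- cohort_config(n_patients = 5, seed = 1)
  # minimum severity: no ARDS/sepsis diagnosis events, survival
  for (ss in 1:20) {
    r <- generate_patient(-Inf, cfg, stream_seed = ss)
    expect_false(any(r$diagnoses$category %in%
                       c("ARDS", "SEPSIS_OR_SEPTIC_SHOCK")))
    expect_false(r$died_in_hospital)
  }
  # maximum severity: the SpO2 trajectory attains a value below 91%
  for (ss in 1:100) {
    r <- generate_patient(Inf, cfg, stream_seed = ss)
    spo2 <- r$observations$value[r$observations$feature == "spo2"]
    expect_true(min(spo2) < 91)
  }
})

test_that("records satisfy the encounter invariants", {
  co <- fixture_cohort(400, seed = 33)
  for (r in co) {
    los <- as.numeric(difftime(r$discharge_time, r$admission_time,
                               units = "hours"))
    expect_gte(los, 2)
    expect_lte(los, 24 * 90)
    expect_true(all(is.finite(r$observations$value)))
    expect_true(all(r$observations$datetime >= r$admission_time &
                      r$observations$datetime <= r$discharge_time))
    expect_true(all(r$diagnoses$category %in%
                      c("ARDS", "SEPSIS_OR_SEPTIC_SHOCK", "HEART_FAILURE",
                        "COVID19", "OTHER")))
  }
})

test_that("latent severity couples monotonically to outcomes", {
  co <- fixture_cohort()
  lab <- fixture_labels()
  sev <- vapply(co, function(r) r$latent_severity, numeric(1))
  lab <- lab[match(vapply(co, `[[`, "", "patient_id"), lab$patient_id), ]
  expect_gt(cor(sev, lab$death_12), 0)
  expect_gt(cor(sev, lab$ards_5), 0)
  expect_gt(cor(sev, lab$hypox_8), 0)
})

test_that("derived label prevalences match their calibration targets", {
  lab <- fixture_labels()
  n <- nrow(lab)
  targets <- attr(fixture_cohort(), "config")$prevalence_targets
  for (tg in label_names()) {
    p <- targets[[tg]]
    tol <- 3 * sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(lab[[tg]]) - p), tol + 1e-12, label = tg)
  }
})

test_that("the CSV trio round-trips through the ingest reader", {
  co <- fixture_cohort(40, seed = 55)
  dir <- withr::local_tempdir()
  write_cohort_csv(co, dir)
  back <- read_cohort_csv(dir)
  expect_length(back, length(co))
  byid <- setNames(back, vapply(back, `[[`, "", "patient_id"))
  for (r in co) {
    b <- byid[[r$patient_id]]
    expect_identical(b$sex, r$sex)
    expect_equal(b$age, r$age)
    expect_identical(b$died_in_hospital, r$died_in_hospital)
    expect_equal(as.numeric(b$admission_time), as.numeric(r$admission_time))
    expect_equal(as.numeric(b$discharge_time), as.numeric(r$discharge_time))
    ro <- r$observations[order(r$observations$datetime, r$observations$feature,
                               r$observations$value), ]
    bo <- b$observations[order(b$observations$datetime, b$observations$feature,
                               b$observations$value), ]
    expect_equal(bo$value, ro$value)
    expect_identical(bo$feature, ro$feature)
    expect_equal(as.numeric(bo$datetime), as.numeric(ro$datetime))
    expect_equal(sort(b$diagnoses$category), sort(r$diagnoses$category))
    expect_identical(b$covid_pcr_results$result, r$covid_pcr_results$result)
  }
})
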
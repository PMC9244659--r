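# The 13 outcome definitions, timing class, and their invariants.

.lab_vec <- function(ls) as.logical(ls[label_names()])

test_that("worked examples compose the definitions correctly", {
  base_spo2 <- data.frame(feature = "spo2", value = c(97, 89, 95),
                          hours = c(1, 30, 60))
  # ARDS code + min SpO2 89, no heart-failure code: all five ARDS labels
  rec <- make_complete_record(required_at = 1, extra = base_spo2,
    diagnoses = data.frame(category = "ARDS", hours = 50))
  at <- determine_algotime(rec, split = "train_val")
  ls <- derive_labels(rec, at)
  expect_true(all(ls[c("ards_1", "ards_2", "ards_3", "ards_4", "ards_5")]))
  expect_true(all(ls[c("hypox_8", "hypox_9", "hypox_10", "hypox_11")]))
  expect_false(any(ls[c("sepsis_6", "sepsis_7", "death_12", "covid_13")]))

  # heart-failure code before the ARDS code switches off ards_3/ards_4 only
  rec2 <- make_complete_record(required_at = 1, extra = base_spo2,
    diagnoses = data.frame(category = c("ARDS", "HEART_FAILURE"),
                           hours = c(50, 10)))
  ls2 <- derive_labels(rec2, determine_algotime(rec2, split = "train_val"))
  expect_true(all(ls2[c("ards_1", "ards_2", "ards_5")]))
  expect_false(ls2[["ards_3"]])
  expect_false(ls2[["ards_4"]])

  # heart-failure code after the ARDS code does not
  rec2b <- make_complete_record(required_at = 1, extra = base_spo2,
    diagnoses = data.frame(category = c("ARDS", "HEART_FAILURE"),
                           hours = c(50, 90)))
  ls2b <- derive_labels(rec2b, determine_algotime(rec2b, split = "train_val"))
  expect_true(ls2b[["ards_3"]])

  # hypoxemia only, dip strictly before algotime: hypox_8/9 but not 10/11
  rec3 <- make_complete_record(required_at = 2,
    extra = data.frame(feature = "spo2", value = c(88, 97),
                       hours = c(1, 30)))
  at3 <- determine_algotime(rec3, split = "train_val")
  ls3 <- derive_labels(rec3, at3)
  expect_true(ls3[["hypox_8"]])
  expect_true(ls3[["hypox_9"]])
  expect_false(ls3[["hypox_10"]])
  expect_false(ls3[["hypox_11"]])
  expect_false(any(ls3[paste0("ards_", 1:5)]))

  # sepsis needs the code; SIRS > 2 separates sepsis_6 from sepsis_7
  rec4 <- make_complete_record(required_at = 1,
    extra = data.frame(feature = c("heart_rate", "resp_rate", "temperature",
                                   "wbc"),
                       value = c(120, 25, 39, 14), hours = rep(12, 4)),
    diagnoses = data.frame(category = "SEPSIS_OR_SEPTIC_SHOCK", hours = 13))
  ls4 <- derive_labels(rec4, determine_algotime(rec4, split = "train_val"))
  expect_true(ls4[["sepsis_6"]])
  expect_true(ls4[["sepsis_7"]])
  rec5 <- make_complete_record(required_at = 1,
    diagnoses = data.frame(category = "SEPSIS_OR_SEPTIC_SHOCK", hours = 13))
  ls5 <- derive_labels(rec5, determine_algotime(rec5, split = "train_val"))
  expect_false(ls5[["sepsis_6"]])
  expect_true(ls5[["sepsis_7"]])

  # COVID via positive PCR during stay, or diagnosis within 7 days
  rec6 <- make_complete_record(required_at = 1,
    pcr = data.frame(hours = 5, result = "positive"))
  expect_true(derive_labels(rec6, determine_algotime(rec6, split = "train_val"))[["covid_13"]])
  rec7 <- make_complete_record(required_at = 1, los_hours = 400,
    diagnoses = data.frame(category = "COVID19", hours = 24 * 8))
  expect_false(derive_labels(rec7, determine_algotime(rec7, split = "train_val"))[["covid_13"]])
  rec8 <- make_complete_record(required_at = 1,
    diagnoses = data.frame(category = "COVID19", hours = -24 * 6))
  expect_true(derive_labels(rec8, determine_algotime(rec8, split = "train_val"))[["covid_13"]])
})

test_that("strict thresholds: SpO2 of exactly 91 or 96 does not qualify", {
  # a minimum of exactly 96 clears both thresholds
  rec <- make_complete_record(required_at = 1,
    extra = data.frame(feature = "spo2", value = 96, hours = 5))
  ls <- derive_labels(rec, determine_algotime(rec, split = "train_val"))
  expect_false(ls[["hypox_8"]])
  expect_false(ls[["hypox_9"]])
  # a minimum of exactly 91 is not below 91, but is below 96
  rec2 <- make_complete_record(required_at = 1,
    extra = data.frame(feature = "spo2", value = 91, hours = 5))
  ls2 <- derive_labels(rec2, determine_algotime(rec2, split = "train_val"))
  expect_false(ls2[["hypox_8"]])
  expect_true(ls2[["hypox_9"]])
})

test_that("diagnosis timing is early/late/none with ties late", {
  spo2 <- data.frame(feature = "spo2", value = 88, hours = 20)
  mk <- function(dx_minutes_after_algotime) {
    # algotime = 1 h + 40 min = 100 min after admission
    make_complete_record(required_at = 1, extra = spo2,
      diagnoses = data.frame(category = "ARDS",
                             hours = (100 + dx_minutes_after_algotime) / 60))
  }
  at <- function(r) determine_algotime(r, split = "train_val")
  expect_identical(classify_diagnosis_timing(mk(-1), at(mk(-1))), "early")
  expect_identical(classify_diagnosis_timing(mk(+1), at(mk(+1))), "late")
  expect_identical(classify_diagnosis_timing(mk(0), at(mk(0))), "late")
  no_ards <- make_complete_record(required_at = 1, extra = spo2)
  expect_identical(classify_diagnosis_timing(no_ards, at(no_ards)), "none")
  # ards_1 asserted but no event timestamp -> data-integrity error
  rec_bad <- make_complete_record(required_at = 1, extra = spo2)
  expect_error(classify_diagnosis_timing(rec_bad, at(rec_bad), ards_1 = TRUE),
               "no ARDS diagnosis event")
})

test_that("label implications hold across a generated cohort", {
  lab <- fixture_labels()
  expect_true(all(lab$ards_1 <= lab$ards_2))
  expect_true(all(lab$ards_3 <= lab$ards_1))
  expect_true(all(lab$ards_4 <= lab$ards_2))
  expect_true(all(lab$ards_1 <= lab$ards_5))
  expect_true(all(lab$hypox_8 <= lab$hypox_9))
  expect_true(all(lab$hypox_10 <= lab$hypox_8))
  expect_true(all(lab$hypox_11 <= lab$hypox_9))
  expect_true(all(lab$sepsis_6 <= lab$sepsis_7))
})

test_that("derivation is invariant to observation shuffling", {
  co <- fixture_cohort(30, seed = 81)
  for (r in co[1:10]) {
    at <- determine_algotime(r, split = "train_val")
    ls1 <- derive_labels(r, at)
    set.seed(1)
    r2 <- r
    r2$observations <- r$observations[sample.int(nrow(r$observations)), ]
    expect_identical(.lab_vec(derive_labels(r2, at)), .lab_vec(ls1))
  }
})

test_that("lowering SpO2 can only switch hypoxemia/ARDS labels on", {
  co <- fixture_cohort(30, seed = 81)
  affected <- c("ards_1", "ards_2", "ards_3", "ards_4",
                "hypox_8", "hypox_9", "hypox_10", "hypox_11")
  for (r in co[1:10]) {
    at <- determine_algotime(r, split = "train_val")
    before <- derive_labels(r, at)
    r2 <- r
    is_spo2 <- r2$observations$feature == "spo2"
    r2$observations$value[is_spo2] <- r2$observations$value[is_spo2] - 8
    after <- derive_labels(r2, at)
    expect_true(all(after[affected] >= before[affected]))
  }
})

test_that("records without SpO2 yield all-false hypoxemia labels", {
  req_no_spo2 <- setdiff(ardswatch:::required_features(), "spo2")
  tab <- normal_ranges()
  rec <- make_record(obs = data.frame(
    feature = req_no_spo2, value = tab$mu[match(req_no_spo2, tab$feature)],
    hours = 1))
  ls <- derive_labels(rec, determine_algotime(rec, split = "train_val"))
  expect_false(any(ls[c("hypox_8", "hypox_9", "hypox_10", "hypox_11")]))
})
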
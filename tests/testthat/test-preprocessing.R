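# Chronologization, SIRS, algotime and the 51x64 input matrix.

test_that("chronologize sorts per feature and conserves events", {
  rec <- make_record(obs = data.frame(
    feature = c("heart_rate", "heart_rate"), value = c(80, 90),
    hours = c(10, 5) / 60))
  ch <- chronologize(rec)
  expect_equal(ch$features$heart_rate$values, c(90, 80))
  expect_equal(as.numeric(diff(ch$features$heart_rate$datetimes)) > 0, TRUE)

  empty <- make_record()
  che <- chronologize(empty)
  expect_true(che$no_data)
  expect_length(che$features, 0)

  # brute-force filter-and-sort oracle on random records
  set.seed(9)
  for (i in 1:100) {
    nf <- sample(3:6, 1)
    obs <- data.frame(
      feature = sample(c("heart_rate", "spo2", "wbc", "glucose"), nf * 4,
                       replace = TRUE),
      value = rnorm(nf * 4, 50), hours = runif(nf * 4, 0, 48))
    rec <- make_record(obs = obs)
    ch <- chronologize(rec)
    expect_equal(sum(vapply(ch$features, function(f) length(f$values), 0L)),
                 nrow(obs))
    for (f in names(ch$features)) {
      sel <- obs[obs$feature == f, ]
      sel <- sel[order(sel$hours), ]
      expect_equal(ch$features[[f]]$values, sel$value)
    }
    expect_equal(as.numeric(ch$start_of_care),
                 as.numeric(rec$admission_time) + min(obs$hours) * 3600)
  }
})

test_that("SIRS counts consensus criteria with missing as non-contributing", {
  expect_identical(compute_sirs(95, 22, 38.5, 13), 4L)
  expect_identical(compute_sirs(70, 14, 37.0, 7), 0L)
  expect_identical(compute_sirs(NA, NA, NA, NA), 0L)
  expect_identical(compute_sirs(91, NA, 35.9, NA), 2L)
  expect_identical(compute_sirs(90, 20, 38, 12), 0L)   # strict thresholds
  expect_identical(compute_sirs(NA, 21, NA, 3.9), 2L)
  # vectorized over bins
  expect_identical(compute_sirs(c(95, 70), c(22, 14), c(38.5, 37), c(13, 7)),
                   c(4L, 0L))
})

test_that("algotime follows the required-features rule with its defaults", {
  # all required present; last first-measurement at 100 min
  req <- ardswatch:::required_features()
  obs <- data.frame(feature = req, value = 50,
                    hours = c(rep(0.5, length(req) - 1), 100 / 60))
  rec <- make_record(obs = obs)
  at <- determine_algotime(rec, split = "train_val")
  expect_identical(at$source, "required-features-rule")
  expect_equal(as.numeric(at$algotime),
               as.numeric(rec$admission_time) + 140 * 60)

  # missing creatinine: train/val defaults to admission + 8 h
  obs2 <- obs[obs$feature != "creatinine", ]
  rec2 <- make_record(obs = obs2)
  at2 <- determine_algotime(rec2, split = "train_val")
  expect_identical(at2$source, "default-8h")
  expect_equal(as.numeric(at2$algotime),
               as.numeric(rec2$admission_time) + 480 * 60)

  # same record in the test split is excluded, not defaulted
  at3 <- determine_algotime(rec2, split = "test")
  expect_identical(at3$source, "excluded")
  expect_true(is.na(at3$algotime))
})

test_that("input matrix geometry: shape, padding, truncation, last-wins", {
  rec <- make_complete_record(required_at = 1,
    extra = data.frame(feature = "heart_rate", value = c(70, 85),
                       hours = c(2.6, 2.7)))
  at <- determine_algotime(rec, split = "train_val")
  tn <- build_feature_tensor(rec, at)
  expect_equal(dim(tn$matrix), c(51, 64))

  # start of care 40 min before algotime -> 3 data columns, 61 padding
  pad_cols <- which(colSums(abs(tn$matrix)) == 0)
  expect_equal(max(pad_cols), 61)
  expect_true(all(tn$matrix[, 1:61] == 0))
  expect_true(all(colSums(abs(tn$matrix[, 62:64])) > 0))

  # two heart-rate values in one bin: the later one occupies the cell
  rec2 <- make_complete_record(required_at = 30,
    extra = data.frame(feature = "heart_rate", value = c(70, 85),
                       hours = c(30.05, 30.10)))
  at2 <- determine_algotime(rec2, split = "train_val")
  tn2 <- build_feature_tensor(rec2, at2)
  tab <- normal_ranges()
  mu <- tab$mu[tab$feature == "heart_rate"]
  sg <- tab$sigma[tab$feature == "heart_rate"]
  hr_row <- tn2$matrix["heart_rate", ]
  expect_true(any(abs(hr_row - (85 - mu) / sg) < 1e-12))
  expect_false(any(abs(hr_row - (70 - mu) / sg) < 1e-12))

  # more than 64 bins of history: only the most recent 64 appear
  rec3 <- make_complete_record(required_at = 300,
    extra = data.frame(feature = "glucose", value = 100, hours = 1))
  at3 <- determine_algotime(rec3, split = "train_val")
  tn3 <- build_feature_tensor(rec3, at3)
  expect_equal(dim(tn3$matrix), c(51, 64))
  expect_equal(sum(tn3$matrix["mask_glucose", ]), 0)  # truncated away

  # idempotence
  expect_identical(build_feature_tensor(rec, at)$matrix, tn$matrix)

  # errors
  expect_error(build_feature_tensor(make_record(), at), "no observations")
  early <- as.POSIXct("2020-12-31 00:00:00", tz = "UTC")
  expect_error(build_feature_tensor(rec, early), "precedes start of care")
})

test_that("binning agrees with a brute-force windowing oracle", {
  set.seed(17)
  tab <- normal_ranges()
  for (i in 1:40) {
    n_obs <- sample(5:60, 1)
    feats <- sample(setdiff(feature_names(), "sirs"), n_obs, replace = TRUE)
    hours <- runif(n_obs, 0, 40)
    vals <- runif(n_obs, 1, 200)
    rec <- make_complete_record(required_at = 0.2,
      extra = data.frame(feature = feats, value = vals, hours = hours))
    at <- determine_algotime(rec, split = "train_val")
    tn <- build_feature_tensor(rec, at)
    # oracle: explicit per-bin group-by + take-last over the last 64 bins
    at_s <- as.numeric(at$algotime)
    obs <- rec$observations
    for (f in unique(feats)) {
      sel <- obs[obs$feature == f, ]
      t_s <- as.numeric(sel$datetime)
      expected <- rep(0, 64); emask <- rep(0, 64)
      for (k in 1:64) {
        hi <- at_s - (64 - k) * 1200; lo <- hi - 1200
        in_bin <- which(t_s > lo & t_s <= hi)
        if (length(in_bin)) {
          last <- in_bin[which.max(t_s[in_bin])]
          mu <- tab$mu[tab$feature == f]; sg <- tab$sigma[tab$feature == f]
          expected[k] <- (sel$value[last] - mu) / sg
          emask[k] <- 1
        }
      }
      expect_equal(unname(tn$matrix[f, ]), expected, tolerance = 1e-12)
      expect_equal(unname(tn$matrix[paste0("mask_", f), ]), emask)
    }
  }
})

test_that("mask/value pairing holds on generated encounters", {
  co <- fixture_cohort(60, seed = 71)
  ts <- build_tensor_set(co, "train_val")
  tv <- feature_names()
  for (tn in ts$tensors) {
    m <- tn$matrix
    expect_equal(dim(m), c(51, 64))
    masks <- m[paste0("mask_", tv), ]
    vals <- m[tv, ]
    expect_true(all(masks %in% c(0, 1)))
    expect_true(all(vals[masks == 0] == 0))
  }
})

test_that("SIRS row is recomputed per bin from forward-filled components", {
  rec <- make_complete_record(required_at = 0.2,
    extra = data.frame(feature = c("heart_rate", "resp_rate", "temperature",
                                   "wbc"),
                       value = c(120, 25, 39, 14), hours = rep(20.5, 4)))
  at <- as.POSIXct(as.numeric(rec$admission_time) + 21 * 3600 + 20 * 60,
                   origin = "1970-01-01", tz = "UTC")
  tn <- build_feature_tensor(rec, at)
  sirs <- tn$matrix["sirs", ]
  tab <- normal_ranges()
  mu <- tab$mu[tab$feature == "sirs"]; sg <- tab$sigma[tab$feature == "sirs"]
  # before the abnormal set: normal values from the required panel -> 0
  # after hour 20.5 (forward-filled): all four criteria met -> score 4
  expect_equal(unname(sirs[64]), (4 - mu) / sg)
  expect_equal(unname(tn$matrix["mask_sirs", 64]), 1)
})
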
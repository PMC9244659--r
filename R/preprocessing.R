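# Raw records -> normalized, masked, fixed-width input matrices.
#
# The input matrix has 51 rows (age, male, female, 24 time-varying features,
# 24 availability masks) and 64 columns of 20-minute bins whose right edge
# is the per-encounter prediction time ("algotime"), so the model never sees
# data past its prediction time.

#' Reorder a record's observations chronologically per feature
#'
#' @param record a `patient_record`.
#' @return list with `features` (per feature, a list of equal-length
#'   `values`, `units`, `datetimes`, sorted by time), `start_of_care` (the
#'   earliest vital/lab timestamp, `NA` when there is none) and `no_data`.
#' @export
chronologize <- function(record) {
  obs <- record$observations
  if (is.null(obs) || nrow(obs) == 0) {
    return(list(features = list(), start_of_care = as.POSIXct(NA),
                no_data = TRUE))
  }
  ord <- order(obs$datetime)
  obs <- obs[ord, , drop = FALSE]
  feats <- split(seq_len(nrow(obs)), obs$feature)
  features <- lapply(feats, function(i) {
    list(values = obs$value[i], units = obs$unit[i],
         datetimes = obs$datetime[i])
  })
  list(features = features, start_of_care = obs$datetime[1], no_data = FALSE)
}

#' Systemic inflammatory response syndrome (SIRS) score
#'
#' Count of satisfied consensus criteria among: temperature > 38 or < 36
#' degC; heart rate > 90/min; respiratory rate > 20/min; white cell count
#' > 12 or < 4 x10^9/L. Missing components contribute 0, so the score is
#' always defined in \[0, 4\]. Vectorized over its arguments.
#'
#' @param heart_rate,respiratory_rate,temperature,wbc most recent values at
#'   the evaluation point; `NA` means not yet measured.
#' @return integer score(s) in \[0, 4\].
#' @export
compute_sirs <- function(heart_rate = NA, respiratory_rate = NA,
                         temperature = NA, wbc = NA) {
  crit <- function(x) !is.na(x) & x
  as.integer(crit(temperature > 38 | temperature < 36) +
             crit(heart_rate > 90) +
             crit(respiratory_rate > 20) +
             crit(wbc > 12 | wbc < 4))
}

#' Determine the per-encounter prediction time
#'
#' The prediction time is 40 minutes after the first time at which every
#' required feature has been measured at least once. Training/validation
#' records missing a required feature fall back to admission + 8 h; test
#' records missing one are excluded (signalled, never defaulted).
#'
#' @param record a `patient_record`.
#' @param required character vector of required observation features.
#' @param split `"train_val"` or `"test"`.
#' @return class `algotime_result`: list with `algotime` (POSIXct, `NA` when
#'   excluded) and `source` (`"required-features-rule"`, `"default-8h"` or
#'   `"excluded"`).
#' @export
determine_algotime <- function(record, required = required_features(),
                               split = c("train_val", "test")) {
  split <- match.arg(split)
  chron <- chronologize(record)
  firsts <- vapply(required, function(f) {
    e <- chron$features[[f]]
    if (is.null(e)) NA_real_ else as.numeric(e$datetimes[1])
  }, numeric(1))
  if (!anyNA(firsts)) {
    at <- as.POSIXct(max(firsts) + 40 * 60, origin = "1970-01-01", tz = "UTC")
    res <- list(algotime = at, source = "required-features-rule")
  } else if (split == "train_val") {
    res <- list(algotime = record$admission_time + 8 * 3600,
                source = "default-8h")
  } else {
    res <- list(algotime = as.POSIXct(NA), source = "excluded")
  }
  structure(res, class = "algotime_result")
}

#' Build the 51 x 64 normalized, masked input matrix for one encounter
#'
#' Columns are the 64 consecutive 20-minute bins ending at `algotime`
#' (`algotime` sits at the right edge of the last column). Within a bin the
#' most recent measurement of a feature wins. The SIRS row is recomputed per
#' bin from the forward-filled most recent components (its mask is 1 once
#' any component has been observed). History shorter than 64 bins is
#' zero-padded on the left in every row, including the demographic rows;
#' longer history is truncated to the most recent 64 bins.
#'
#' @param record a `patient_record`.
#' @param algotime POSIXct prediction time, or an `algotime_result`.
#' @param table normal-range table.
#' @return class `feature_tensor`: list with `matrix` (51 x 64), plus
#'   `patient_id`, `algotime`, `source`.
#' @export
build_feature_tensor <- function(record, algotime, table = normal_ranges()) {
  source <- "supplied"
  if (inherits(algotime, "algotime_result")) {
    source <- algotime$source
    algotime <- algotime$algotime
  }
  if (is.na(algotime)) stop("algotime is NA (excluded record)")
  chron <- chronologize(record)
  if (chron$no_data) stop("record has no observations")
  if (as.numeric(algotime) < as.numeric(chron$start_of_care))
    stop("algotime precedes start of care")

  tv <- feature_names()                     # 24, sirs last
  obs_feats <- setdiff(tv, "sirs")
  at <- as.numeric(algotime)
  obs <- record$observations
  t_sec <- as.numeric(obs$datetime)
  off_min <- (at - t_sec) / 60

  vals <- matrix(0, nrow = length(tv), ncol = N_TIMESTEPS,
                 dimnames = list(tv, NULL))
  mask <- matrix(0, nrow = length(tv), ncol = N_TIMESTEPS,
                 dimnames = list(tv, NULL))

  inwin <- which(off_min >= 0 & off_min < N_TIMESTEPS * BIN_MINUTES &
                   obs$feature %in% obs_feats)
  if (length(inwin)) {
    ord <- inwin[order(t_sec[inwin])]       # ascending: later overwrites
    bin <- N_TIMESTEPS - floor(off_min[ord] / BIN_MINUTES)
    row <- match(obs$feature[ord], tv)
    idx <- cbind(row, bin)
    vals[idx] <- obs$value[ord]
    mask[idx] <- 1
  }

  # SIRS per bin from forward-filled components over all history <= bin edge.
  edges <- at - (N_TIMESTEPS - seq_len(N_TIMESTEPS)) * BIN_MINUTES * 60
  comp <- list(heart_rate = NA, resp_rate = NA, temperature = NA, wbc = NA)
  comp_at_edge <- lapply(names(comp), function(f) {
    sel <- which(obs$feature == f & t_sec <= at)
    if (!length(sel)) return(rep(NA_real_, N_TIMESTEPS))
    o <- sel[order(t_sec[sel])]
    i <- findInterval(edges, t_sec[o])
    ifelse(i == 0, NA_real_, obs$value[o][pmax(i, 1)])
  })
  names(comp_at_edge) <- names(comp)
  sirs_mask <- as.numeric(Reduce(`|`, lapply(comp_at_edge, function(v) !is.na(v))))
  sirs_score <- compute_sirs(comp_at_edge$heart_rate, comp_at_edge$resp_rate,
                             comp_at_edge$temperature, comp_at_edge$wbc)
  vals["sirs", ] <- sirs_score * sirs_mask
  mask["sirs", ] <- sirs_mask

  norm_vals <- normalize_matrix(ifelse(mask == 1, vals, NA), tv, table)

  m <- matrix(0, nrow = N_INPUT_ROWS, ncol = N_TIMESTEPS)
  rownames(m) <- c("age", "male", "female", tv, paste0("mask_", tv))
  m["age", ] <- (record$age - AGE_MU) / AGE_SIGMA
  m["male", ] <- as.numeric(record$sex == "male")
  m["female", ] <- as.numeric(record$sex == "female")
  m[tv, ] <- norm_vals
  m[paste0("mask_", tv), ] <- mask

  # Left padding: columns whose bin edge precedes the start of care are
  # all-zero in every row (demographics included).
  pad <- edges < as.numeric(chron$start_of_care)
  m[, pad] <- 0

  structure(list(matrix = m, patient_id = record$patient_id,
                 algotime = as.POSIXct(at, origin = "1970-01-01", tz = "UTC"),
                 source = source),
            class = "feature_tensor")
}

#' Build input matrices for a whole cohort
#'
#' Applies [determine_algotime()] and [build_feature_tensor()] to every
#' record, honouring the split rule (test records lacking required features
#' are excluded rather than defaulted).
#'
#' @param cohort an `ehr_cohort` or list of records.
#' @param split `"train_val"` or `"test"`.
#' @param table normal-range table.
#' @return list with `tensors` (list of `feature_tensor`), `algotimes`
#'   (named POSIXct) and `excluded` (character patient ids).
#' @export
build_tensor_set <- function(cohort, split = "train_val",
                             table = normal_ranges()) {
  tensors <- list()
  algotimes <- c()
  excluded <- character(0)
  for (rec in cohort) {
    at <- determine_algotime(rec, split = split)
    if (at$source == "excluded") {
      excluded <- c(excluded, rec$patient_id)
      next
    }
    tn <- tryCatch(build_feature_tensor(rec, at, table), error = function(e) NULL)
    if (is.null(tn)) {
      excluded <- c(excluded, rec$patient_id)
      next
    }
    tensors[[rec$patient_id]] <- tn
    algotimes[rec$patient_id] <- at$algotime
  }
  list(tensors = tensors,
       algotimes = as.POSIXct(algotimes, origin = "1970-01-01", tz = "UTC"),
       excluded = excluded)
}

# Stack a list of feature_tensor into the (B x 51) per-timestep matrices the
# network consumes.
tensor_stack <- function(tensors) {
  B <- length(tensors)
  arr <- array(0, dim = c(B, N_INPUT_ROWS, N_TIMESTEPS))
  for (i in seq_len(B)) arr[i, , ] <- tensors[[i]]$matrix
  dimnames(arr) <- list(vapply(tensors, function(t) t$patient_id, ""),
                        rownames(tensors[[1]]$matrix), NULL)
  arr
}
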
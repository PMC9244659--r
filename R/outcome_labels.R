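# Derivation of the 13 binary outcome labels and the early/late
# diagnosis-timing class.
#
# Label semantics (thresholds are strict, "below 91%" = < 91):
#   ards_5  ARDS code present
#   ards_1  ards_5 and stay-wide min SpO2 < 91
#   ards_2  ards_5 and stay-wide min SpO2 < 96
#   ards_3  ards_1 and no heart-failure code before the first ARDS code
#   ards_4  ards_2 and no heart-failure code before the first ARDS code
#   sepsis_7 sepsis/septic-shock code
#   sepsis_6 sepsis_7 and maximum SIRS over the stay > 2
#   hypox_8/9   any SpO2 < 91 / < 96 during the stay
#   hypox_10/11 any SpO2 < 91 / < 96 strictly after algotime
#   death_12 in-hospital death
#   covid_13 positive PCR during the stay, or COVID diagnosis within
#            7 days of admission (either side)

# Maximum SIRS over the stay: recompute the score at every time a component
# updates, with components forward-filled.
.max_sirs <- function(record) {
  obs <- record$observations
  comps <- c("heart_rate", "resp_rate", "temperature", "wbc")
  sel <- obs$feature %in% comps
  if (!any(sel)) return(0L)
  o <- obs[sel, , drop = FALSE]
  o <- o[order(o$datetime), , drop = FALSE]
  t <- as.numeric(o$datetime)
  cur <- lapply(comps, function(f) {
    i <- which(o$feature == f)
    if (!length(i)) return(rep(NA_real_, nrow(o)))
    j <- findInterval(seq_len(nrow(o)), i)
    ifelse(j == 0, NA_real_, o$value[i][pmax(j, 1)])
  })
  names(cur) <- comps
  max(compute_sirs(cur$heart_rate, cur$resp_rate, cur$temperature, cur$wbc))
}

.first_dx_time <- function(record, category) {
  d <- record$diagnoses
  sel <- d$category == category
  if (!any(sel)) return(NULL)
  min(d$datetime[sel])
}

#' Derive the 13 binary outcome labels for an encounter
#'
#' @param record a `patient_record`.
#' @param algotime POSIXct prediction time or an `algotime_result` (used
#'   only by the post-algotime hypoxemia labels and the timing class).
#' @return class `label_set`: named logical vector of the 13 labels plus a
#'   `diagnosis_timing` attribute in `{early, late, none}`.
#' @export
derive_labels <- function(record, algotime) {
  if (inherits(algotime, "algotime_result")) algotime <- algotime$algotime
  if (is.na(algotime)) stop("algotime is NA")
  obs <- record$observations
  spo2 <- obs$value[obs$feature == "spo2"]
  spo2_t <- obs$datetime[obs$feature == "spo2"]
  min_spo2 <- if (length(spo2)) min(spo2) else Inf
  after <- spo2[as.numeric(spo2_t) > as.numeric(algotime)]
  min_after <- if (length(after)) min(after) else Inf

  ards_code <- !is.null(.first_dx_time(record, "ARDS"))
  sepsis_code <- !is.null(.first_dx_time(record, "SEPSIS_OR_SEPTIC_SHOCK"))

  no_prior_hf <- TRUE
  if (ards_code) {
    t_ards <- .first_dx_time(record, "ARDS")
    d <- record$diagnoses
    hf <- d$datetime[d$category == "HEART_FAILURE"]
    no_prior_hf <- !any(as.numeric(hf) < as.numeric(t_ards))
  }

  pcr_pos <- FALSE
  pcr <- record$covid_pcr_results
  if (!is.null(pcr) && nrow(pcr) > 0) {
    during <- as.numeric(pcr$datetime) >= as.numeric(record$admission_time) &
      as.numeric(pcr$datetime) <= as.numeric(record$discharge_time)
    pcr_pos <- any(pcr$result == "positive" & during)
  }
  covid_dx <- FALSE
  t_cov <- .first_dx_time(record, "COVID19")
  if (!is.null(t_cov)) {
    covid_dx <- abs(as.numeric(t_cov) - as.numeric(record$admission_time)) <=
      7 * 86400
  }

  lab <- c(
    ards_1 = ards_code && min_spo2 < 91,
    ards_2 = ards_code && min_spo2 < 96,
    ards_3 = ards_code && min_spo2 < 91 && no_prior_hf,
    ards_4 = ards_code && min_spo2 < 96 && no_prior_hf,
    ards_5 = ards_code,
    sepsis_6 = sepsis_code && .max_sirs(record) > 2,
    sepsis_7 = sepsis_code,
    hypox_8 = min_spo2 < 91,
    hypox_9 = min_spo2 < 96,
    hypox_10 = min_after < 91,
    hypox_11 = min_after < 96,
    death_12 = isTRUE(record$died_in_hospital),
    covid_13 = pcr_pos || covid_dx)
  structure(lab, class = "label_set",
            diagnosis_timing = classify_diagnosis_timing(record, algotime,
                                                         ards_1 = lab[["ards_1"]]))
}

#' Classify an ARDS diagnosis as early or late relative to the prediction
#'
#' `none` when the encounter is not ARDS-1 positive; `early` when the first
#' ARDS diagnosis code precedes algotime; `late` otherwise (a code entered
#' exactly at algotime counts as late, since the prediction cannot have
#' preceded it).
#'
#' @param record a `patient_record`.
#' @param algotime POSIXct or `algotime_result`.
#' @param ards_1 optionally, the precomputed ARDS-1 label.
#' @return `"early"`, `"late"` or `"none"`.
#' @export
classify_diagnosis_timing <- function(record, algotime, ards_1 = NULL) {
  if (inherits(algotime, "algotime_result")) algotime <- algotime$algotime
  if (is.null(ards_1)) {
    obs <- record$observations
    spo2 <- obs$value[obs$feature == "spo2"]
    min_spo2 <- if (length(spo2)) min(spo2) else Inf
    ards_1 <- !is.null(.first_dx_time(record, "ARDS")) && min_spo2 < 91
  }
  if (!isTRUE(ards_1)) return("none")
  t_ards <- .first_dx_time(record, "ARDS")
  if (is.null(t_ards)) stop("ARDS-1 positive record has no ARDS diagnosis event")
  if (as.numeric(t_ards) < as.numeric(algotime)) "early" else "late"
}

#' Derive labels for a whole cohort as a data frame
#'
#' @param cohort an `ehr_cohort`.
#' @param algotimes named POSIXct vector of prediction times (as produced by
#'   [build_tensor_set()]), or `NULL` to apply [determine_algotime()] with
#'   the train/val default rule.
#' @return data.frame: `patient_id`, 13 binary label columns (0/1),
#'   `diagnosis_timing`.
#' @export
cohort_labels <- function(cohort, algotimes = NULL) {
  rows <- lapply(cohort, function(rec) {
    at <- if (is.null(algotimes)) {
      determine_algotime(rec, split = "train_val")
    } else {
      if (!rec$patient_id %in% names(algotimes)) return(NULL)
      algotimes[[rec$patient_id]]
    }
    if (inherits(at, "algotime_result") && at$source == "excluded") return(NULL)
    if (!inherits(at, "algotime_result") && is.na(at)) return(NULL)
    ls <- derive_labels(rec, at)
    df <- as.data.frame(as.list(as.integer(ls)))
    names(df) <- label_names()
    cbind(data.frame(patient_id = rec$patient_id, stringsAsFactors = FALSE),
          df,
          data.frame(diagnosis_timing = attr(ls, "diagnosis_timing"),
                     stringsAsFactors = FALSE))
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
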
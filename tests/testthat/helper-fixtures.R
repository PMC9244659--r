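# Shared fixtures, built in code and cached for the test session.

.fix <- new.env(parent = emptyenv())

# A moderately sized cohort reused by several property suites.
fixture_cohort <- function(n = 2000, seed = 101) {
  key <- paste0("cohort_", n, "_", seed)
  if (is.null(.fix[[key]])) {
    .fix[[key]] <- generate_cohort(cohort_config(n_patients = n, seed = seed))
  }
  .fix[[key]]
}

fixture_labels <- function(n = 2000, seed = 101) {
  key <- paste0("labels_", n, "_", seed)
  if (is.null(.fix[[key]])) {
    .fix[[key]] <- cohort_labels(fixture_cohort(n, seed))
  }
  .fix[[key]]
}

# Hand-built record: explicit observation and diagnosis times in hours
# since admission.
make_record <- function(obs = NULL, diagnoses = NULL, died = FALSE,
                        age = 60, sex = "male", los_hours = 120,
                        pcr = NULL, id = "T1") {
  adm <- as.POSIXct("2021-01-01 00:00:00", tz = "UTC")
  o <- if (is.null(obs)) {
    data.frame(feature = character(0), value = numeric(0),
               unit = character(0),
               datetime = as.POSIXct(character(0), tz = "UTC"))
  } else {
    data.frame(feature = obs$feature, value = obs$value,
               unit = "u", datetime = adm + obs$hours * 3600,
               stringsAsFactors = FALSE)
  }
  d <- if (is.null(diagnoses)) {
    data.frame(category = character(0),
               datetime = as.POSIXct(character(0), tz = "UTC"))
  } else {
    data.frame(category = diagnoses$category,
               datetime = adm + diagnoses$hours * 3600,
               stringsAsFactors = FALSE)
  }
  p <- if (is.null(pcr)) {
    data.frame(datetime = as.POSIXct(character(0), tz = "UTC"),
               result = character(0), stringsAsFactors = FALSE)
  } else {
    data.frame(datetime = adm + pcr$hours * 3600, result = pcr$result,
               stringsAsFactors = FALSE)
  }
  structure(list(patient_id = id, age = age, sex = sex,
                 admission_time = adm,
                 discharge_time = adm + los_hours * 3600,
                 died_in_hospital = died, covid_pcr_results = p,
                 observations = o, diagnoses = d,
                 latent_severity = NA_real_),
            class = "patient_record")
}

# Record with one observation of every required feature at the given hour,
# so algotime is deterministic.
make_complete_record <- function(required_at = 1, extra = NULL, ...) {
  req <- ardswatch:::required_features()
  tab <- normal_ranges()
  obs <- data.frame(feature = req,
                    value = tab$mu[match(req, tab$feature)],
                    hours = required_at)
  if (!is.null(extra)) obs <- rbind(obs, extra)
  make_record(obs = obs, ...)
}

# Tiny separable supervised fixture: class decided by a clean signal in one
# input row, for learner sanity checks.
fixture_separable <- function(n = 160, seed = 5) {
  set.seed(seed)
  D <- ardswatch:::N_INPUT_ROWS; Tn <- ardswatch:::N_TIMESTEPS
  y <- rep(c(0, 1), length.out = n)
  X <- array(rnorm(n * D * Tn, 0, 0.1), dim = c(n, D, Tn))
  for (i in seq_len(n)) X[i, 4, ] <- X[i, 4, ] + ifelse(y[i] == 1, 2, -2)
  tv <- feature_names()
  dimnames(X) <- list(paste0("S", seq_len(n)),
                      c("age", "male", "female", tv, paste0("mask_", tv)),
                      NULL)
  # masks all 1 so no cell is treated as missing downstream
  X[, paste0("mask_", tv), ] <- 1
  Y <- matrix(y, n, 13, dimnames = list(NULL, label_names()))
  list(X = X, Y = Y, y = y)
}

small_mt_config <- function(n_targets = 1L, seed = 1L, ...) {
  mt_config(n_targets = n_targets,
            target_subset = label_names()[seq_len(n_targets)],
            hidden_units = 8L, gru_layers = 2L, fc1_dim = 8L,
            attn_dims = c(6L, 4L), max_epochs = 5L, patience = 5L,
            batch_size = 32L, learning_rate = 0.01, seed = seed, ...)
}
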
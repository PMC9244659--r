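#' @keywords internal
#' @useDynLib ardswatch, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Canonical feature registry. Row order of the model input matrix is fixed:
# row 1 age, rows 2-3 male/female indicators, rows 4-27 the 24 time-varying
# features in the order of the normal-range table (7 vitals, 16 labs, SIRS),
# rows 28-51 the matching availability masks.

.aw_env <- new.env(parent = emptyenv())

#' Normal-range table for the time-varying input features
#'
#' Returns the versioned table of clinical normal ranges shipped with the
#' package. For each feature the center of the normal range is used as an
#' approximate mean and half the range width as an approximate SD; these
#' drive the fixed input normalization (values are mapped to
#' `(x - mu) / sigma`, so the high bound of the range maps to +1).
#'
#' @return A data.frame with columns `feature`, `kind` (vital/lab/computed),
#'   `unit`, `low`, `high`, `required` (logical; part of the algotime rule),
#'   `mu`, `sigma`.
#' @export
normal_ranges <- function() {
  if (is.null(.aw_env$ranges)) {
    path <- system.file("extdata", "normal_ranges.csv", package = "ardswatch")
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    stopifnot(all(tab$low < tab$high))
    tab$mu <- (tab$low + tab$high) / 2
    tab$sigma <- (tab$high - tab$low) / 2
    .aw_env$ranges <- tab
  }
  .aw_env$ranges
}

#' Names of the time-varying features, in input-matrix row order
#' @param kind optional filter: "vital", "lab" or "computed".
#' @return character vector of feature names.
#' @export
feature_names <- function(kind = NULL) {
  tab <- normal_ranges()
  if (!is.null(kind)) tab <- tab[tab$kind %in% kind, , drop = FALSE]
  tab$feature
}

# Observation features that must each be measured at least once before the
# prediction time can be set by the data-driven rule (age and sex are
# demographics and always available, so the rule reduces to these).
required_features <- function() {
  tab <- normal_ranges()
  tab$feature[tab$required]
}

# Constants of the input-matrix geometry.
N_TIMESTEPS <- 64L
BIN_MINUTES <- 20
N_TIMEVARYING <- 24L
N_INPUT_ROWS <- 51L # 1 age + 2 sex + 24 values + 24 masks
AGE_MU <- 50
AGE_SIGMA <- 20

#' The thirteen outcome label names, in canonical order
#' @return character vector of length 13.
#' @export
label_names <- function() {
  c("ards_1", "ards_2", "ards_3", "ards_4", "ards_5",
    "sepsis_6", "sepsis_7",
    "hypox_8", "hypox_9", "hypox_10", "hypox_11",
    "death_12", "covid_13")
}

#' Normalize a raw measurement against its clinical normal range
#'
#' Maps a value to `(x - mu_f) / sigma_f` where `mu_f` is the center of the
#' feature's normal range and `sigma_f` half its width. A missing value
#' (`NA`) is encoded as 0 with availability mask 0.
#'
#' @param feature feature name (a row of [normal_ranges()]).
#' @param raw_value numeric value in the feature's clinical units, or `NA`.
#' @param table a normal-range table; defaults to the shipped one.
#' @return list with `value` (normalized, 0 if missing) and `mask` (0/1).
#' @export
normalize_value <- function(feature, raw_value, table = normal_ranges()) {
  i <- match(feature, table$feature)
  if (is.na(i)) stop("unknown feature: ", feature)
  if (length(raw_value) != 1 || (!is.na(raw_value) && !is.finite(raw_value)))
    stop("raw_value must be a single finite number or NA")
  if (is.na(raw_value)) return(list(value = 0, mask = 0L))
  list(value = (raw_value - table$mu[i]) / table$sigma[i], mask = 1L)
}

# Vectorized normalization for a whole named value matrix (features x bins);
# NA -> 0. Used by the tensor builder.
normalize_matrix <- function(values, features, table = normal_ranges()) {
  idx <- match(features, table$feature)
  stopifnot(!anyNA(idx))
  out <- (values - table$mu[idx]) / table$sigma[idx]
  out[is.na(out)] <- 0
  out
}
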
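# Attention-based interpretability: per-patient attention weight rows and
# the feature z-profile at the most-attended timestep.

#' Attention heat-map matrix for a random patient sample
#'
#' Runs the forward pass on `n_sample` randomly chosen patients and returns
#' their attention weight rows unchanged (no renormalization), one row per
#' patient.
#'
#' @param model a `trained_mt_model`.
#' @param tensors list of `feature_tensor` (or a stacked array).
#' @param n_sample number of patients to sample.
#' @param seed sampling seed.
#' @return matrix `n_sample x 64` with patient ids as row names; rows sum
#'   to 1.
#' @export
attention_heatmap_data <- function(model, tensors, n_sample = 50L, seed = 1L) {
  if (!inherits(model, "trained_mt_model")) stop("invalid state: untrained model")
  if (is.list(tensors)) {
    if (n_sample > length(tensors)) stop("n_sample exceeds cohort size")
    set.seed(seed)
    sel <- sample.int(length(tensors), n_sample)
    X <- tensor_stack(tensors[sel])
  } else {
    if (n_sample > dim(tensors)[1]) stop("n_sample exceeds cohort size")
    set.seed(seed)
    sel <- sample.int(dim(tensors)[1], n_sample)
    X <- tensors[sel, , , drop = FALSE]
  }
  fw <- mt_forward(X, model)
  W <- fw$attention_weights
  rownames(W) <- dimnames(X)[[1]]
  W
}

#' Feature z-profile at the most-attended timestep
#'
#' Finds the timestep with the highest attention weight (earliest on ties)
#' and reads off the normalized time-varying feature column there. Because
#' the input matrix is normalized against clinical normal ranges, each entry
#' reads as a z-score; masked (unmeasured) features are 0.
#'
#' @param model a `trained_mt_model`.
#' @param tensor a single `feature_tensor`.
#' @return class `attention_profile`: list with `patient_id`, `weights`
#'   (64), `argmax_step` (1-based), `feature_z` (named, 24 time-varying
#'   features).
#' @export
max_attention_feature_profile <- function(model, tensor) {
  if (!inherits(model, "trained_mt_model")) stop("invalid state: untrained model")
  stopifnot(inherits(tensor, "feature_tensor"))
  X <- tensor_stack(list(tensor))
  fw <- mt_forward(X, model)
  w <- fw$attention_weights[1, ]
  step <- which.max(w)            # which.max takes the first maximum
  tv <- feature_names()
  structure(list(patient_id = tensor$patient_id,
                 weights = w,
                 argmax_step = step,
                 feature_z = tensor$matrix[tv, step]),
            class = "attention_profile")
}

#' Export interpretability matrices as TSV
#'
#' Writes the attention heat-map matrix and the per-patient max-attention
#' feature z-profiles for the same sample.
#'
#' @param model a `trained_mt_model`.
#' @param tensors list of `feature_tensor`.
#' @param dir output directory.
#' @param n_sample,seed as in [attention_heatmap_data()].
#' @return `dir`, invisibly.
#' @export
export_interpretability <- function(model, tensors, dir, n_sample = 50L,
                                    seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  W <- attention_heatmap_data(model, tensors, n_sample, seed)
  utils::write.table(W, file.path(dir, "attention_weights.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  ids <- rownames(W)
  byid <- stats::setNames(tensors, vapply(tensors, `[[`, "", "patient_id"))
  zs <- t(vapply(ids, function(id) {
    pr <- max_attention_feature_profile(model, byid[[id]])
    pr$feature_z
  }, numeric(N_TIMEVARYING)))
  utils::write.table(zs, file.path(dir, "max_attention_feature_z.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  invisible(dir)
}
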
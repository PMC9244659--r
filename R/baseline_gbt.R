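# One-vs-all gradient-boosted-tree comparator on the identical feature
# matrices, flattened feature-major with masked cells passed as native
# missing values (the tree learner handles them directly).

#' Baseline model configuration
#'
#' @param max_depth,eta hyperparameter grids (all combinations are tried;
#'   each target keeps its best validation-AUROC point).
#' @param n_rounds boosting rounds.
#' @param seed integer seed.
#' @return class `baseline_config`.
#' @export
baseline_config <- function(max_depth = c(3L, 6L), eta = c(0.1, 0.3),
                            n_rounds = 50L, seed = 1L) {
  grid <- expand.grid(max_depth = max_depth, eta = eta)
  if (nrow(grid) == 0) stop("hyperparameter grid must be non-empty")
  structure(list(grid = grid, n_rounds = as.integer(n_rounds),
                 seed = as.integer(seed)),
            class = "baseline_config")
}

#' Flatten input matrices for the tree learner
#'
#' Feature-major (row-major) flattening of the 51 x 64 matrix into a
#' 3264-length vector per patient; cells of time-varying rows whose
#' availability mask is 0 become `NA` so the learner sees true
#' missingness rather than imputed zeros.
#'
#' @param tensors list of `feature_tensor` or stacked array.
#' @return numeric matrix (patients x 3264) with `NA` for missing cells.
#' @export
flatten_tensors <- function(tensors) {
  X <- if (is.list(tensors)) tensor_stack(tensors) else tensors
  B <- dim(X)[1]
  rows <- dimnames(X)[[2]]
  tv <- feature_names()
  tv_idx <- match(tv, rows)
  mask_idx <- match(paste0("mask_", tv), rows)
  out <- matrix(NA_real_, B, dim(X)[2] * dim(X)[3])
  for (i in seq_len(B)) {
    m <- X[i, , ]
    vals <- m
    vals[tv_idx, ][m[mask_idx, ] == 0] <- NA
    out[i, ] <- as.vector(t(vals))
  }
  rownames(out) <- dimnames(X)[[1]]
  colnames(out) <- paste0(rep(rows, each = dim(X)[3]), "_t",
                          rep(seq_len(dim(X)[3]), times = length(rows)))
  out
}

#' Train one-vs-all gradient-boosted scorers for every target
#'
#' One binary booster per target; each target's grid point is chosen by
#' validation AUROC. Targets that are single-class in the training data are
#' skipped with a warning and replaced by a prevalence-constant scorer.
#'
#' @param train_x,val_x flattened matrices from [flatten_tensors()] (or
#'   tensor lists, flattened on the fly).
#' @param train_y,val_y 0/1 label matrices with named columns.
#' @param config a [baseline_config()].
#' @return class `gbt_baseline`: list of per-target scorers plus chosen
#'   grid points.
#' @export
train_one_vs_all <- function(train_x, train_y, val_x, val_y,
                             config = baseline_config()) {
  if (is.list(train_x)) train_x <- flatten_tensors(train_x)
  if (is.list(val_x)) val_x <- flatten_tensors(val_x)
  train_y <- as.matrix(train_y); val_y <- as.matrix(val_y)
  targets <- colnames(train_y)
  scorers <- vector("list", length(targets))
  names(scorers) <- targets
  chosen <- list()
  for (tg in targets) {
    y <- train_y[, tg]
    if (length(unique(y)) < 2) {
      warning("target ", tg, " is single-class in training data; ",
              "using a prevalence-constant scorer")
      scorers[[tg]] <- list(type = "constant", value = mean(y))
      chosen[[tg]] <- NA
      next
    }
    dtrain <- xgboost::xgb.DMatrix(train_x, label = y, missing = NA)
    best <- NULL
    for (gi in seq_len(nrow(config$grid))) {
      set.seed(config$seed)
      bst <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = config$grid$max_depth[gi],
                      eta = config$grid$eta[gi],
                      nthread = 1, seed = config$seed),
        data = dtrain, nrounds = config$n_rounds, verbose = 0)
      pv <- stats::predict(bst, xgboost::xgb.DMatrix(val_x, missing = NA))
      auc <- if (length(unique(val_y[, tg])) < 2) NA_real_
             else auroc(pv, val_y[, tg])
      if (is.null(best) || (!is.na(auc) && auc > best$auc)) {
        best <- list(model = bst, auc = auc, grid = config$grid[gi, ])
      }
    }
    scorers[[tg]] <- list(type = "xgb", model = best$model)
    chosen[[tg]] <- best$grid
  }
  structure(list(scorers = scorers, chosen = chosen, config = config),
            class = "gbt_baseline")
}

#' Score patients with the one-vs-all baseline
#'
#' @param baseline a `gbt_baseline`.
#' @param x flattened matrix (or tensor list).
#' @return matrix (patients x targets) of predicted probabilities.
#' @export
predict_one_vs_all <- function(baseline, x) {
  if (is.list(x)) x <- flatten_tensors(x)
  out <- vapply(names(baseline$scorers), function(tg) {
    sc <- baseline$scorers[[tg]]
    if (sc$type == "constant") rep(sc$value, nrow(x))
    else stats::predict(sc$model, xgboost::xgb.DMatrix(x, missing = NA))
  }, numeric(nrow(x)))
  rownames(out) <- rownames(x)
  out
}
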
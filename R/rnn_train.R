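# Training loop (Adam, minibatches, early stopping on ARDS-1 validation
# AUROC) and the target-ablation protocol.

# Elementwise recursion over parameter trees (params / grads / Adam state
# share one structure).
.tree_map <- function(f, ...) {
  trees <- list(...)
  if (is.list(trees[[1]])) {
    out <- vector("list", length(trees[[1]]))
    names(out) <- names(trees[[1]])
    for (i in seq_along(out))
      out[[i]] <- do.call(.tree_map, c(list(f), lapply(trees, `[[`, i)))
    out
  } else {
    do.call(f, trees)
  }
}

.adam_init <- function(params) {
  list(m = .tree_map(function(p) p * 0, params),
       v = .tree_map(function(p) p * 0, params),
       t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- .tree_map(function(v, g) beta2 * v + (1 - beta2) * g * g,
                       state$v, grads)
  c1 <- 1 / (1 - beta1^state$t)
  c2 <- 1 / (1 - beta2^state$t)
  params <- .tree_map(function(p, m, v) p - lr * (m * c1) / (sqrt(v * c2) + eps),
                      params, state$m, state$v)
  list(params = params, state = state)
}

# Rescale a gradient tree to a maximum global L2 norm (standard recurrent
# network stabilization).
.clip_global_norm <- function(grads, max_norm) {
  total <- 0
  .tree_map(function(g) { total <<- total + sum(g * g); g }, grads)
  nrm <- sqrt(total)
  if (is.finite(nrm) && nrm > max_norm) {
    sc <- max_norm / nrm
    grads <- .tree_map(function(g) g * sc, grads)
  }
  grads
}

# One optimization step on a batch (fused compiled forward+backward);
# returns loss and the updated parameters/optimizer state.
.train_batch <- function(params, X, Y, state, lr, clip_norm = 1) {
  bg <- .aw_batch_grad_cpp(params, X, Y)
  grads <- bg$grads
  if (is.finite(clip_norm)) grads <- .clip_global_norm(grads, clip_norm)
  upd <- .adam_step(params, grads, state, lr)
  list(params = upd$params, state = upd$state, loss = bg$loss)
}

#' Train the multitask network with early stopping
#'
#' Runs minibatch Adam for up to `config$max_epochs` epochs; after each
#' epoch the ARDS-1 validation AUROC is recorded, and the parameters of the
#' epoch with the highest value are kept (earliest epoch on ties). Training
#' stops once `config$patience` epochs pass without improvement. The whole
#' run is a pure function of the data and `config$seed`.
#'
#' @param train_x,val_x (batch x 51 x 64) arrays (or lists of
#'   `feature_tensor`).
#' @param train_y,val_y 0/1 label matrices with columns named after
#'   `config$target_subset` (extra columns are subset away).
#' @param config an [mt_config()].
#' @param verbose print per-epoch progress.
#' @return class `trained_mt_model`: list with `params`, `config`,
#'   `training_history` (per-epoch validation AUROC for ards_1),
#'   `selected_epoch`, `train_loss` (per epoch mean).
#' @export
mt_train <- function(train_x, train_y, val_x, val_y, config = mt_config(),
                     verbose = FALSE) {
  if (is.list(train_x) && inherits(train_x[[1]], "feature_tensor"))
    train_x <- tensor_stack(train_x)
  if (is.list(val_x) && inherits(val_x[[1]], "feature_tensor"))
    val_x <- tensor_stack(val_x)
  train_y <- as.matrix(train_y)[, config$target_subset, drop = FALSE]
  val_y <- as.matrix(val_y)[, config$target_subset, drop = FALSE]
  if (length(unique(val_y[, "ards_1"])) < 2)
    stop("cannot evaluate: ards_1 validation labels are single-class")

  set.seed(config$seed)
  params <- .init_params(config, input_dim = dim(train_x)[2])
  state <- .adam_init(params)
  n <- dim(train_x)[1]
  bs <- min(config$batch_size, n)
  history <- numeric(0)
  losses <- numeric(0)
  best_auc <- -Inf; best_epoch <- 0L; best_params <- params

  for (epoch in seq_len(config$max_epochs)) {
    idx <- sample.int(n)
    ep_loss <- 0; nb <- 0
    for (start in seq(1, n, by = bs)) {
      sel <- idx[start:min(start + bs - 1, n)]
      Xb <- train_x[sel, , , drop = FALSE]
      Yb <- train_y[sel, , drop = FALSE]
      res <- .train_batch(params, Xb, Yb, state, config$learning_rate)
      params <- res$params; state <- res$state
      ep_loss <- ep_loss + res$loss; nb <- nb + 1
    }
    losses <- c(losses, ep_loss / nb)
    vp <- .aw_forward_cpp(params, val_x)$probabilities
    auc <- auroc(vp[, match("ards_1", config$target_subset)],
                 val_y[, "ards_1"])
    history <- c(history, auc)
    if (auc > best_auc) {
      best_auc <- auc; best_epoch <- epoch; best_params <- params
    }
    if (verbose)
      message(sprintf("epoch %d: loss %.4f, val ards_1 AUROC %.4f",
                      epoch, ep_loss / nb, auc))
    if (epoch - best_epoch >= config$patience) break
  }
  structure(list(params = best_params, config = config,
                 training_history = history,
                 selected_epoch = best_epoch,
                 train_loss = losses),
            class = "trained_mt_model")
}

#' @export
print.trained_mt_model <- function(x, ...) {
  cat(sprintf(paste0("<trained_mt_model: %d targets, %d GRU layers x %d units, ",
                     "best epoch %d/%d (val ards_1 AUROC %.3f)>\n"),
              x$config$n_targets, x$config$gru_layers, x$config$hidden_units,
              x$selected_epoch, length(x$training_history),
              max(x$training_history)))
  invisible(x)
}

#' Target-ablation series: 13, 11, 9, 7, 5 training targets
#'
#' Trains the full 13-target network, scores every target on the test set,
#' then successively removes the two lowest-AUROC targets (never removing
#' `ards_1`) and retrains, producing the 13/11/9/7/5-target series.
#'
#' @param train_x,train_y,val_x,val_y,test_x,test_y data arrays/matrices as
#'   in [mt_train()]; label matrices must carry all 13 label columns.
#' @param config a 13-target [mt_config()] used as the template for every
#'   stage.
#' @param verbose print stage progress.
#' @return list of stages, each with `n_targets`, `target_subset`, `model`,
#'   `test_auroc` (named vector).
#' @export
ablation_series <- function(train_x, train_y, val_x, val_y, test_x, test_y,
                            config = mt_config(), verbose = FALSE) {
  stopifnot(config$n_targets == 13L)
  if (is.list(test_x) && inherits(test_x[[1]], "feature_tensor"))
    test_x <- tensor_stack(test_x)
  test_y <- as.matrix(test_y)
  subset <- config$target_subset
  stages <- list()
  for (k in c(13L, 11L, 9L, 7L, 5L)) {
    cfg <- config
    cfg$n_targets <- k
    cfg$target_subset <- subset
    model <- mt_train(train_x, train_y, val_x, val_y, cfg, verbose = verbose)
    probs <- mt_forward(test_x, model)$probabilities
    aucs <- vapply(seq_along(subset), function(j) {
      y <- test_y[, subset[j]]
      if (length(unique(y)) < 2) return(NA_real_)
      auroc(probs[, j], y)
    }, numeric(1))
    names(aucs) <- subset
    stages[[as.character(k)]] <- list(n_targets = k, target_subset = subset,
                                      model = model, test_auroc = aucs)
    if (verbose) message(sprintf("stage %d targets: ards_1 test AUROC %.3f",
                                 k, aucs[["ards_1"]]))
    if (k > 5L) {
      removable <- setdiff(subset, "ards_1")
      ranks <- aucs[removable]
      ranks[is.na(ranks)] <- -Inf
      drop2 <- removable[order(ranks)][1:2]
      subset <- setdiff(subset, drop2)
    }
  }
  stages
}

#' Serialize a trained model to a portable JSON archive
#'
#' Weights, config and training history are stored as plain JSON so the
#' archive is text-only and platform independent.
#'
#' @param model a `trained_mt_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_mt_model <- function(model, path) {
  payload <- list(params = model$params,
                  config = unclass(model$config),
                  training_history = model$training_history,
                  selected_epoch = model$selected_epoch,
                  train_loss = model$train_loss)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       pretty = FALSE)
  invisible(path)
}

#' Load a model saved by [save_mt_model()]
#' @param path archive path.
#' @return a `trained_mt_model`.
#' @export
load_mt_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE,
                                 simplifyMatrix = TRUE)
  cfg <- payload$config
  config <- mt_config(n_targets = cfg$n_targets,
                      target_subset = cfg$target_subset,
                      hidden_units = cfg$hidden_units,
                      gru_layers = cfg$gru_layers, fc1_dim = cfg$fc1_dim,
                      attn_dims = cfg$attn_dims, max_epochs = cfg$max_epochs,
                      patience = cfg$patience,
                      learning_rate = cfg$learning_rate,
                      batch_size = cfg$batch_size, seed = cfg$seed)
  structure(list(params = payload$params, config = config,
                 training_history = payload$training_history,
                 selected_epoch = payload$selected_epoch,
                 train_loss = payload$train_loss),
            class = "trained_mt_model")
}
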
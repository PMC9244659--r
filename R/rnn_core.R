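# Multitask attention-GRU: parameter container, forward pass with cache,
# and exact reverse-mode gradients (backpropagation through time).
#
# Architecture, per encounter:
#   51-row input -> learned elementwise normalization a*(v-mu)/sigma + b
#   -> stacked GRU layers over the 64 timesteps
#   -> additive attention over the deepest layer's hidden states:
#        score(h_n, h_i) = K' tanh(Wa prelu(Wb [h_n, h_i]))
#      softmax scores -> weights -> context vector (weighted hidden sum)
#   -> concat(context, last hidden) -> FC1 (penultimate embedding, PReLU)
#   -> FC2 -> one logit per target -> sigmoid.
# The sigma of the normalization layer is parameterized as exp(log-sigma),
# so it stays strictly positive by construction.

#' Model configuration for the multitask recurrent network
#'
#' @param n_targets number of output targets (the first, canonical target
#'   `ards_1` must always be present).
#' @param target_subset ordered label names the network is trained on.
#' @param hidden_units GRU hidden state width per layer.
#' @param gru_layers number of stacked GRU layers.
#' @param fc1_dim width of the first fully connected layer (the penultimate
#'   patient embedding used for clustering).
#' @param attn_dims widths `c(d_b, d_a)` of the attention scorer's two
#'   linear maps; defaults scale with `hidden_units`.
#' @param max_epochs,patience early-stopping schedule (epochs without
#'   improvement in ARDS-1 validation AUROC before stopping).
#' @param learning_rate,batch_size Adam step size and minibatch size.
#' @param seed seed controlling initialization and batch shuffling.
#' @return an object of class `mt_config`.
#' @export
mt_config <- function(n_targets = 13L,
                      target_subset = label_names()[seq_len(n_targets)],
                      hidden_units = 128L, gru_layers = 4L, fc1_dim = 64L,
                      attn_dims = c(max(hidden_units %/% 2L, 2L),
                                    max(hidden_units %/% 4L, 2L)),
                      max_epochs = 15L, patience = 3L,
                      learning_rate = 1e-3, batch_size = 128L, seed = 1L) {
  if (n_targets == 13L && missing(target_subset)) target_subset <- label_names()
  if (length(target_subset) != n_targets)
    stop("target_subset length must equal n_targets")
  if (!"ards_1" %in% target_subset)
    stop("target_subset must contain ards_1 (early stopping depends on it)")
  if (fc1_dim <= 0) stop("fc1_dim must be positive")
  structure(list(n_targets = as.integer(n_targets),
                 target_subset = target_subset,
                 hidden_units = as.integer(hidden_units),
                 gru_layers = as.integer(gru_layers),
                 fc1_dim = as.integer(fc1_dim),
                 attn_dims = as.integer(attn_dims),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "mt_config")
}

#' Learned elementwise input normalization
#'
#' Applies `a * (v - mu) / sigma + b` elementwise; the four parameter
#' vectors are learned jointly with the network.
#'
#' @param v input vector (or matrix with inputs in columns, batch in rows).
#' @param params list with `a`, `b`, `mu`, `sigma` vectors.
#' @return normalized vector/matrix.
#' @export
learned_normalize <- function(v, params) {
  if (any(params$sigma <= 0)) stop("invalid state: sigma must be positive")
  if (is.matrix(v)) {
    B <- nrow(v)
    rp <- function(p) rep(p, each = B)
    rp(params$a) * (v - rp(params$mu)) / rp(params$sigma) + rp(params$b)
  } else {
    params$a * (v - params$mu) / params$sigma + params$b
  }
}

.prelu <- function(x, a) pmax(x, 0) + a * pmin(x, 0)
.prelu_grad <- function(x, a) (x > 0) + a * (x <= 0)

#' Additive attention score for one (query, key) pair
#'
#' `score = K' tanh(Wa prelu(Wb [h_n, h_i]))` with a shared PReLU slope.
#'
#' @param h_n deepest-layer hidden state at the final timestep.
#' @param h_i deepest-layer hidden state at timestep i.
#' @param K,W_a,W_b attention parameters.
#' @param alpha PReLU negative slope.
#' @return scalar score.
#' @export
attention_score <- function(h_n, h_i, K, W_a, W_b, alpha = 0.25) {
  u <- c(h_n, h_i)
  if (ncol(W_b) != length(u)) stop("dimension mismatch: W_b vs [h_n, h_i]")
  if (ncol(W_a) != nrow(W_b)) stop("dimension mismatch: W_a vs W_b")
  if (length(K) != nrow(W_a)) stop("dimension mismatch: K vs W_a")
  s <- sum(K * tanh(W_a %*% .prelu(W_b %*% u, alpha)))
  if (!is.finite(s)) stop("non-finite attention score")
  s
}

#' Softmax normalization of attention scores into weights
#' @param scores numeric vector of finite scores.
#' @return nonnegative weights summing to 1.
#' @export
attention_weights <- function(scores) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  e <- exp(scores - max(scores))
  e / sum(e)
}

#' Mean multilabel binary cross-entropy
#'
#' Mean over batch and targets of the binary cross-entropy between
#' `sigmoid(logits)` and the 0/1 labels, computed in a numerically stable
#' softplus form.
#'
#' @param logits numeric matrix (batch x targets) or vector.
#' @param labels same shape, entries in `{0, 1}`.
#' @return nonnegative scalar.
#' @export
multilabel_loss <- function(logits, labels) {
  if (length(logits) != length(labels)) stop("shape mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  mean(pmax(logits, 0) - logits * labels + log1p(exp(-abs(logits))))
}

# ---- parameter initialization ----

.init_params <- function(config, input_dim = N_INPUT_ROWS) {
  H <- config$hidden_units
  L <- config$gru_layers
  db <- config$attn_dims[1]; da <- config$attn_dims[2]
  Fd <- config$fc1_dim
  Tg <- config$n_targets
  U <- function(r, c, scale) matrix(stats::runif(r * c, -scale, scale), r, c)
  # Orthogonal recurrent matrices: standard stabilization for deep RNNs.
  orth <- function(H) qr.Q(qr(matrix(stats::rnorm(H * H), H, H)))
  k <- 1 / sqrt(H)
  gru <- vector("list", L)
  for (l in seq_len(L)) {
    Din <- if (l == 1) input_dim else H
    gru[[l]] <- list(Wz = U(H, Din, k), Wr = U(H, Din, k), Wn = U(H, Din, k),
                     Uz = orth(H), Ur = orth(H), Un = orth(H),
                     bz = rep(1, H), br = rep(0, H), bn = rep(0, H))
  }
  list(norm = list(a = rep(1, input_dim), b = rep(0, input_dim),
                   mu = rep(0, input_dim), ls = rep(0, input_dim)),
       gru = gru,
       attn = list(Wb = U(db, 2 * H, 1 / sqrt(2 * H)),
                   Wa = U(da, db, 1 / sqrt(db)),
                   K = stats::runif(da, -1 / sqrt(da), 1 / sqrt(da)),
                   alpha = 0.25),
       fc = list(W1 = U(Fd, 2 * H, 1 / sqrt(2 * H)), b1 = rep(0, Fd),
                 W2 = U(Tg, Fd, 1 / sqrt(Fd)), b2 = rep(0, Tg),
                 alpha = 0.25))
}

.addb <- function(M, b) M + rep(b, each = nrow(M))

# ---- forward pass ----
# X: array (B x D x T). Returns output plus (optionally) the full cache
# needed for the backward pass.

.mt_forward_core <- function(params, X, keep_cache = FALSE) {
  B <- dim(X)[1]; D <- dim(X)[2]; Tn <- dim(X)[3]
  L <- length(params$gru)
  H <- nrow(params$gru[[1]]$Uz)
  sig <- exp(params$norm$ls)
  a <- params$norm$a; mu <- params$norm$mu; bb <- params$norm$b

  Xn <- vector("list", Tn)
  Xr <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    x <- X[, , t, drop = FALSE]; dim(x) <- c(B, D)
    Xr[[t]] <- x
    Xn[[t]] <- .addb((x - rep(mu, each = B)) * rep(a / sig, each = B), bb)
  }

  hs <- vector("list", L)   # hs[[l]][[t]]
  zs <- rs <- ns <- gs <- vector("list", L)
  inp <- Xn
  for (l in seq_len(L)) {
    g <- params$gru[[l]]
    h_prev <- matrix(0, B, H)
    hs[[l]] <- zs[[l]] <- rs[[l]] <- ns[[l]] <- gs[[l]] <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      x <- inp[[t]]
      z <- stats::plogis(.addb(tcrossprod(x, g$Wz) + tcrossprod(h_prev, g$Uz), g$bz))
      r <- stats::plogis(.addb(tcrossprod(x, g$Wr) + tcrossprod(h_prev, g$Ur), g$br))
      gg <- tcrossprod(h_prev, g$Un)
      n <- tanh(.addb(tcrossprod(x, g$Wn) + r * gg, g$bn))
      h <- (1 - z) * n + z * h_prev
      zs[[l]][[t]] <- z; rs[[l]][[t]] <- r; ns[[l]][[t]] <- n
      gs[[l]][[t]] <- gg; hs[[l]][[t]] <- h
      h_prev <- h
    }
    inp <- hs[[l]]
  }

  Htop <- hs[[L]]
  hN <- Htop[[Tn]]
  at <- params$attn
  S <- matrix(0, B, Tn)
  Vs <- Ps <- Qs <- Ts <- if (keep_cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    Uc <- cbind(hN, Htop[[t]])
    V <- tcrossprod(Uc, at$Wb)
    P <- .prelu(V, at$alpha)
    Q <- tcrossprod(P, at$Wa)
    Tt <- tanh(Q)
    S[, t] <- Tt %*% at$K
    if (keep_cache) { Vs[[t]] <- V; Ps[[t]] <- P; Qs[[t]] <- Q; Ts[[t]] <- Tt }
  }
  Sm <- S - apply(S, 1, max)
  Wt <- exp(Sm); Wt <- Wt / rowSums(Wt)
  C <- matrix(0, B, H)
  for (t in seq_len(Tn)) C <- C + Wt[, t] * Htop[[t]]

  O <- cbind(C, hN)
  fc <- params$fc
  E1 <- .addb(tcrossprod(O, fc$W1), fc$b1)
  E <- .prelu(E1, fc$alpha)
  Lg <- .addb(tcrossprod(E, fc$W2), fc$b2)

  out <- list(logits = Lg, probabilities = stats::plogis(Lg),
              attention_weights = Wt, context_vector = C,
              penultimate_embedding = E)
  if (keep_cache) {
    out$cache <- list(Xr = Xr, Xn = Xn, hs = hs, zs = zs, rs = rs, ns = ns,
                      gs = gs, Vs = Vs, Ps = Ps, Qs = Qs, Ts = Ts, S = S,
                      Wt = Wt, C = C, O = O, E1 = E1, E = E, B = B, Tn = Tn,
                      H = H, L = L)
  }
  out
}

# ---- backward pass ----
# dLg: gradient of the scalar loss wrt the logits (B x Tg).
# Returns a gradient list with the same structure as params.

.mt_backward_core <- function(params, cache, dLg) {
  B <- cache$B; Tn <- cache$Tn; H <- cache$H; L <- cache$L
  fc <- params$fc; at <- params$attn
  E <- cache$E; E1 <- cache$E1; O <- cache$O; Wt <- cache$Wt
  Htop <- cache$hs[[L]]
  hN <- Htop[[Tn]]

  g_fc <- list(W2 = crossprod(dLg, E), b2 = colSums(dLg))
  dE <- dLg %*% fc$W2
  dE1 <- dE * .prelu_grad(E1, fc$alpha)
  g_fc$alpha <- sum(dE * E1 * (E1 <= 0))
  g_fc$W1 <- crossprod(dE1, O)
  g_fc$b1 <- colSums(dE1)
  dO <- dE1 %*% fc$W1
  dC <- dO[, seq_len(H), drop = FALSE]
  dhN_extra <- dO[, H + seq_len(H), drop = FALSE]

  # context & softmax
  dWt <- matrix(0, B, Tn)
  for (t in seq_len(Tn)) dWt[, t] <- rowSums(dC * Htop[[t]])
  rowdot <- rowSums(dWt * Wt)
  dS <- Wt * (dWt - rowdot)

  g_at <- list(Wb = matrix(0, nrow(at$Wb), ncol(at$Wb)),
               Wa = matrix(0, nrow(at$Wa), ncol(at$Wa)),
               K = numeric(length(at$K)), alpha = 0)
  dHtop <- vector("list", Tn)
  dhN_acc <- dhN_extra
  for (t in seq_len(Tn)) {
    ds <- dS[, t]
    Tt <- cache$Ts[[t]]; P <- cache$Ps[[t]]; V <- cache$Vs[[t]]
    g_at$K <- g_at$K + as.numeric(crossprod(Tt, ds))
    dTt <- outer(ds, at$K)
    dQ <- dTt * (1 - Tt * Tt)
    g_at$Wa <- g_at$Wa + crossprod(dQ, P)
    dP <- dQ %*% at$Wa
    dV <- dP * .prelu_grad(V, at$alpha)
    g_at$alpha <- g_at$alpha + sum(dP * V * (V <= 0))
    Uc <- cbind(hN, Htop[[t]])
    g_at$Wb <- g_at$Wb + crossprod(dV, Uc)
    dU <- dV %*% at$Wb
    dhN_acc <- dhN_acc + dU[, seq_len(H), drop = FALSE]
    dHtop[[t]] <- Wt[, t] * dC + dU[, H + seq_len(H), drop = FALSE]
  }
  dHtop[[Tn]] <- dHtop[[Tn]] + dhN_acc

  # BPTT through the stacked GRU layers
  g_gru <- vector("list", L)
  dOut <- dHtop
  for (l in rev(seq_len(L))) {
    g <- params$gru[[l]]
    inp <- if (l == 1) cache$Xn else cache$hs[[l - 1]]
    Din <- ncol(inp[[1]])
    gl <- list(Wz = matrix(0, H, Din), Wr = matrix(0, H, Din),
               Wn = matrix(0, H, Din), Uz = matrix(0, H, H),
               Ur = matrix(0, H, H), Un = matrix(0, H, H),
               bz = numeric(H), br = numeric(H), bn = numeric(H))
    dInp <- vector("list", Tn)
    dh_next <- matrix(0, B, H)
    for (t in rev(seq_len(Tn))) {
      dh <- dOut[[t]] + dh_next
      z <- cache$zs[[l]][[t]]; r <- cache$rs[[l]][[t]]
      n <- cache$ns[[l]][[t]]; gg <- cache$gs[[l]][[t]]
      h_prev <- if (t > 1) cache$hs[[l]][[t - 1]] else matrix(0, B, H)
      x <- inp[[t]]
      dz <- dh * (h_prev - n)
      dn <- dh * (1 - z)
      dh_prev <- dh * z
      dan <- dn * (1 - n * n)
      gl$Wn <- gl$Wn + crossprod(dan, x)
      gl$bn <- gl$bn + colSums(dan)
      dx <- dan %*% g$Wn
      dgg <- dan * r
      dr <- dan * gg
      dh_prev <- dh_prev + dgg %*% g$Un
      gl$Un <- gl$Un + crossprod(dgg, h_prev)
      daz <- dz * z * (1 - z)
      dar <- dr * r * (1 - r)
      gl$Wz <- gl$Wz + crossprod(daz, x)
      gl$Wr <- gl$Wr + crossprod(dar, x)
      gl$Uz <- gl$Uz + crossprod(daz, h_prev)
      gl$Ur <- gl$Ur + crossprod(dar, h_prev)
      gl$bz <- gl$bz + colSums(daz)
      gl$br <- gl$br + colSums(dar)
      dx <- dx + daz %*% g$Wz + dar %*% g$Wr
      dh_prev <- dh_prev + daz %*% g$Uz + dar %*% g$Ur
      dInp[[t]] <- dx
      dh_next <- dh_prev
    }
    g_gru[[l]] <- gl
    dOut <- dInp
  }

  # normalization layer
  a <- params$norm$a; mu <- params$norm$mu; sig <- exp(params$norm$ls)
  da <- db <- dmu <- dls <- numeric(length(a))
  for (t in seq_len(Tn)) {
    dXn <- dOut[[t]]
    x <- cache$Xr[[t]]
    xc <- x - rep(mu, each = B)
    da <- da + colSums(dXn * xc) / sig
    db <- db + colSums(dXn)
    dmu <- dmu - colSums(dXn) * a / sig
    dls <- dls - colSums(dXn * xc) * a / sig
  }
  list(norm = list(a = da, b = db, mu = dmu, ls = dls),
       gru = g_gru,
       attn = g_at[c("Wb", "Wa", "K", "alpha")],
       fc = g_fc[c("W1", "b1", "W2", "b2", "alpha")])
}

#' Forward pass of the multitask network
#'
#' @param X a (batch x 51 x 64) array of input matrices (see
#'   [build_feature_tensor()]), or a list of `feature_tensor` objects.
#' @param model a `trained_mt_model` or a raw parameter list.
#' @return list with `logits`, `probabilities` (batch x targets),
#'   `attention_weights` (batch x 64, rows summing to 1), `context_vector`
#'   and `penultimate_embedding`.
#' @export
mt_forward <- function(X, model) {
  params <- if (!is.null(model$params)) model$params else model
  if (is.list(X) && inherits(X[[1]], "feature_tensor")) X <- tensor_stack(X)
  if (length(dim(X)) != 3 || dim(X)[2] != length(params$norm$a))
    stop("input must be a (batch x rows x timesteps) array")
  out <- .aw_forward_cpp(params, X)
  out$last_hidden <- NULL
  out
}
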
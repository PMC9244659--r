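# Network building blocks: normalization, attention, loss, forward pass,
# exact gradients, and the training loop contracts.

test_that("learned normalization matches its closed form", {
  id <- list(a = 1, b = 0, mu = 0, sigma = 1)
  expect_equal(learned_normalize(c(-2, 0, 3), list(a = rep(1, 3), b = rep(0, 3),
                                                   mu = rep(0, 3),
                                                   sigma = rep(1, 3))),
               c(-2, 0, 3))
  expect_equal(learned_normalize(5, list(a = 2, b = 1, mu = 3, sigma = 2)), 3)
  # v = mu forces the output to b
  p <- list(a = 7, b = -0.3, mu = 4.2, sigma = 0.5)
  expect_equal(learned_normalize(4.2, p), -0.3)
  p$sigma <- 0
  expect_error(learned_normalize(1, p), "sigma")
})

test_that("attention score matches a hand-multiplied toy case", {
  # zero K collapses every score to 0
  Wb <- matrix(c(0.3, -0.2, 0.1, 0.4, -0.5, 0.2, 0.6, -0.1), 2, 4)
  Wa <- matrix(c(0.5, -0.3, 0.2, 0.7), 2, 2)
  expect_equal(attention_score(c(1, 2), c(3, -1), c(0, 0), Wa, Wb), 0)
  # identical inputs give identical scores
  K <- c(0.4, -0.6)
  s1 <- attention_score(c(1, 2), c(3, -1), K, Wa, Wb)
  s2 <- attention_score(c(1, 2), c(3, -1), K, Wa, Wb)
  expect_identical(s1, s2)
  # explicit small-matrix arithmetic oracle
  u <- c(1, 2, 3, -1)
  v <- as.numeric(Wb %*% u)
  pre <- ifelse(v > 0, v, 0.25 * v)
  oracle <- sum(K * tanh(as.numeric(Wa %*% pre)))
  expect_equal(s1, oracle)
  expect_error(attention_score(c(1, 2, 3), c(3, -1), K, Wa, Wb),
               "dimension mismatch")
})

test_that("attention weights are a softmax", {
  expect_equal(attention_weights(rep(1.7, 64)), rep(1 / 64, 64))
  expect_equal(attention_weights(0.3), 1)
  expect_equal(attention_weights(c(0, log(3))), c(0.25, 0.75))
  expect_error(attention_weights(c(1, NaN)), "finite")
})

test_that("multilabel loss equals mean binary cross-entropy", {
  expect_equal(multilabel_loss(matrix(0, 2, 2), matrix(c(0, 1, 1, 0), 2, 2)),
               log(2))
  expect_lt(multilabel_loss(matrix(c(50, -50), 1, 2),
                            matrix(c(1, 0), 1, 2)), 1e-10)
  # 2x2 hand-computed scalar BCE
  lg <- matrix(c(0.5, -1, 2, 0), 2, 2)
  y <- matrix(c(1, 0, 0, 1), 2, 2)
  p <- plogis(lg)
  oracle <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(multilabel_loss(lg, y), oracle)
  expect_error(multilabel_loss(lg, matrix(c(1, 0, 2, 1), 2, 2)), "0/1")
})

test_that("forward pass is deterministic, shape-correct and batch-equivariant", {
  set.seed(31)
  cfg <- small_mt_config(n_targets = 3L)
  cfg$target_subset <- c("ards_1", "ards_2", "hypox_8")
  cfg$n_targets <- 3L
  params <- ardswatch:::.init_params(cfg)
  B <- 5
  X <- array(rnorm(B * 51 * 64), dim = c(B, 51, 64))
  f1 <- mt_forward(X, params)
  f2 <- mt_forward(X, params)
  expect_identical(f1, f2)
  expect_equal(dim(f1$logits), c(B, 3))
  expect_true(all(f1$probabilities > 0 & f1$probabilities < 1))
  expect_equal(rowSums(f1$attention_weights), rep(1, B), tolerance = 1e-6)

  # all-zero input still yields normalized attention
  f0 <- mt_forward(array(0, dim = c(1, 51, 64)), params)
  expect_equal(sum(f0$attention_weights), 1, tolerance = 1e-6)

  # permuting patients permutes outputs identically (per-patient oracle)
  perm <- c(3, 1, 5, 2, 4)
  fp <- mt_forward(X[perm, , , drop = FALSE], params)
  expect_equal(fp$logits, f1$logits[perm, ])
  expect_equal(fp$attention_weights, f1$attention_weights[perm, ])
  one <- mt_forward(X[2, , , drop = FALSE], params)
  expect_equal(as.numeric(one$logits), as.numeric(f1$logits[2, ]),
               tolerance = 1e-12)

  expect_error(mt_forward(array(0, dim = c(2, 7, 64)), params),
               "batch x rows x timesteps")
})

test_that("backward pass matches finite differences", {
  set.seed(42)
  cfg <- mt_config(n_targets = 2, target_subset = c("ards_1", "hypox_8"),
                   hidden_units = 5, gru_layers = 3, fc1_dim = 4,
                   attn_dims = c(4, 3))
  params <- ardswatch:::.init_params(cfg, input_dim = 6)
  B <- 3; Tn <- 7
  X <- array(rnorm(B * 6 * Tn), dim = c(B, 6, Tn))
  Y <- matrix(rbinom(B * 2, 1, 0.5), B, 2)
  fw <- ardswatch:::.mt_forward_core(params, X, keep_cache = TRUE)
  grads <- ardswatch:::.mt_backward_core(params, fw$cache,
                                         (fw$probabilities - Y) / length(Y))
  flat_p <- unlist(params); flat_g <- unlist(grads)
  expect_identical(names(flat_p), names(flat_g))
  lossfun <- function(fp) {
    multilabel_loss(
      ardswatch:::.mt_forward_core(relist(fp, params), X)$logits, Y)
  }
  set.seed(1)
  idx <- sort(sample(length(flat_p), 80))
  eps <- 1e-6
  num <- vapply(idx, function(k) {
    up <- flat_p; up[k] <- up[k] + eps
    dn <- flat_p; dn[k] <- dn[k] - eps
    (lossfun(up) - lossfun(dn)) / (2 * eps)
  }, numeric(1))
  rel <- abs(num - flat_g[idx]) / pmax(1e-6, abs(num) + abs(flat_g[idx]))
  expect_lt(max(rel), 1e-3)
})

test_that("one optimization step decreases the loss on a fixed batch", {
  set.seed(7)
  cfg <- small_mt_config(n_targets = 2L)
  cfg$target_subset <- c("ards_1", "ards_2"); cfg$n_targets <- 2L
  params <- ardswatch:::.init_params(cfg)
  X <- array(rnorm(8 * 51 * 64), dim = c(8, 51, 64))
  Y <- matrix(rbinom(16, 1, 0.5), 8, 2)
  state <- ardswatch:::.adam_init(params)
  l0 <- multilabel_loss(ardswatch:::.mt_forward_core(params, X)$logits, Y)
  res <- ardswatch:::.train_batch(params, X, Y, state, lr = 1e-4)
  l1 <- multilabel_loss(ardswatch:::.mt_forward_core(res$params, X)$logits, Y)
  expect_lt(l1, l0)
})

test_that("training honours the early-stopping schedule and determinism", {
  fx <- fixture_separable(n = 96)
  tr <- 1:64; va <- 65:96
  cfg <- small_mt_config(n_targets = 1L, seed = 2)
  cfg$max_epochs <- 1L; cfg$patience <- 0L
  m <- mt_train(fx$X[tr, , ], fx$Y[tr, 1, drop = FALSE],
                fx$X[va, , ], fx$Y[va, 1, drop = FALSE], cfg)
  expect_length(m$training_history, 1)
  expect_identical(m$selected_epoch, 1L)

  cfg2 <- small_mt_config(n_targets = 1L, seed = 2)
  cfg2$max_epochs <- 5L; cfg2$patience <- 5L
  m1 <- mt_train(fx$X[tr, , ], fx$Y[tr, 1, drop = FALSE],
                 fx$X[va, , ], fx$Y[va, 1, drop = FALSE], cfg2)
  m2 <- mt_train(fx$X[tr, , ], fx$Y[tr, 1, drop = FALSE],
                 fx$X[va, , ], fx$Y[va, 1, drop = FALSE], cfg2)
  expect_identical(m1$training_history, m2$training_history)
  expect_identical(m1$params, m2$params)

  # a separable cohort is learned far above chance
  expect_gt(max(m1$training_history), 0.9)

  # single-class validation labels cannot drive early stopping
  y_const <- fx$Y; y_const[, "ards_1"] <- 1
  expect_error(mt_train(fx$X[tr, , ], fx$Y[tr, 1, drop = FALSE],
                        fx$X[va, , ], y_const[va, 1, drop = FALSE], cfg2),
               "single-class")
})

test_that("model archives round-trip through JSON", {
  fx <- fixture_separable(n = 64)
  cfg <- small_mt_config(n_targets = 1L, seed = 3)
  cfg$max_epochs <- 1L; cfg$patience <- 1L
  m <- mt_train(fx$X[1:40, , ], fx$Y[1:40, 1, drop = FALSE],
                fx$X[41:64, , ], fx$Y[41:64, 1, drop = FALSE], cfg)
  path <- withr::local_tempfile(fileext = ".json")
  save_mt_model(m, path)
  m2 <- load_mt_model(path)
  f1 <- mt_forward(fx$X[1:5, , ], m)
  f2 <- mt_forward(fx$X[1:5, , ], m2)
  expect_equal(unname(f1$logits), unname(f2$logits), tolerance = 1e-12)
  expect_equal(m2$training_history, m$training_history)
})

test_that("ablation series follows the 13/11/9/7/5 protocol", {
  set.seed(11)
  n <- 120
  D <- ardswatch:::N_INPUT_ROWS
  X <- array(rnorm(n * D * 64, 0, 0.2), dim = c(n, D, 64))
  sev <- rnorm(n)
  for (i in seq_len(n)) X[i, 4, ] <- X[i, 4, ] + sev[i]
  Y <- vapply(seq_len(13), function(j) {
    as.numeric(plogis(sev * (1 + j / 13) + rnorm(n)) > 0.5)
  }, numeric(n))
  colnames(Y) <- label_names()
  Y[, "ards_1"] <- as.numeric(sev + rnorm(n, 0, 0.5) > 0)
  dimnames(X) <- list(paste0("A", 1:n), NULL, NULL)
  cfg <- small_mt_config(n_targets = 13L, seed = 4)
  cfg$target_subset <- label_names(); cfg$n_targets <- 13L
  cfg$max_epochs <- 2L; cfg$patience <- 2L
  tr <- 1:60; va <- 61:90; te <- 91:120
  st <- ablation_series(X[tr, , ], Y[tr, ], X[va, , ], Y[va, ],
                        X[te, , ], Y[te, ], cfg)
  expect_identical(vapply(st, function(s) s$n_targets, 0L),
                   c(`13` = 13L, `11` = 11L, `9` = 9L, `7` = 7L, `5` = 5L))
  for (s in st) expect_true("ards_1" %in% s$target_subset)
  # removed pair at each step is the argmin-2 of the previous stage's AUROCs
  ks <- c("13", "11", "9", "7")
  for (i in seq_along(ks)) {
    prev <- st[[ks[i]]]
    nxt <- st[[i + 1]]
    removable <- setdiff(prev$target_subset, "ards_1")
    aucs <- prev$test_auroc[removable]
    aucs[is.na(aucs)] <- -Inf
    expected_drop <- removable[order(aucs)][1:2]
    expect_setequal(setdiff(prev$target_subset, nxt$target_subset),
                    expected_drop)
  }
})
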
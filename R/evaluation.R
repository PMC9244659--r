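# AUROC with percentile bootstrap CIs, operating-point selection, and
# model-comparison reporting.

#' Area under the ROC curve
#'
#' Computed via the rank (Mann-Whitney) identity: the probability that a
#' random positive outranks a random negative, with ties counted one half.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 outcome labels (both classes must be present).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("undefined metric: labels are single-class")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Percentile bootstrap confidence interval for the AUROC
#'
#' Resamples patients with replacement `B` times; resamples containing a
#' single outcome class are redrawn. Returns the 2.5 and 97.5 percentiles.
#'
#' @param scores,labels as in [auroc()].
#' @param B number of bootstrap resamples (default 1000).
#' @param seed integer seed; the interval is deterministic given it.
#' @param level confidence level (default 0.95).
#' @return named numeric `c(low, high)`.
#' @export
bootstrap_ci <- function(scores, labels, B = 1000L, seed = 1L, level = 0.95) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2) stop("undefined metric: single-class labels")
  if (B < 1) stop("B must be >= 1")
  set.seed(seed)
  n <- length(scores)
  stat <- numeric(B)
  for (b in seq_len(B)) {
    for (try in 1:1000) {
      i <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[i])) == 2) break
    }
    stat[b] <- auroc(scores[i], labels[i])
  }
  alpha <- (1 - level) / 2
  q <- stats::quantile(stat, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}

#' Operating point at a target sensitivity
#'
#' Chooses the decision threshold that achieves at least the requested
#' sensitivity while maximizing specificity (the highest threshold whose
#' sensitivity still reaches the target; predictions are positive when
#' `score >= threshold`). An unreachable target degenerates to a threshold
#' below all scores with sensitivity 1.
#'
#' @param scores,labels as in [auroc()].
#' @param target_sensitivity required sensitivity in (0, 1).
#' @return list with `threshold`, `sensitivity`, `specificity`.
#' @export
operating_point <- function(scores, labels, target_sensitivity = 0.65) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2) stop("single-class labels")
  if (target_sensitivity <= 0 || target_sensitivity > 1)
    stop("target_sensitivity must be in (0, 1]")
  pos <- labels == 1
  thr <- sort(unique(scores), decreasing = TRUE)
  best <- NULL
  for (t in thr) {
    sens <- mean(scores[pos] >= t)
    if (sens >= target_sensitivity) {
      best <- list(threshold = t, sensitivity = sens,
                   specificity = mean(scores[!pos] < t))
      break
    }
  }
  if (is.null(best)) {
    best <- list(threshold = -Inf, sensitivity = 1,
                 specificity = 0)
  }
  best
}

#' Per-target evaluation report
#'
#' Tabulates AUROC, percentile-bootstrap CI, and the sensitivity/specificity
#' at a fixed-sensitivity operating point for each target.
#'
#' @param scores matrix (patients x targets) of predicted probabilities,
#'   with column names.
#' @param labels 0/1 matrix with matching columns.
#' @param model_name label recorded in the report.
#' @param B bootstrap resamples.
#' @param target_sensitivity operating-point convention.
#' @param seed bootstrap seed.
#' @return class `eval_report`: data.frame with one row per target.
#' @export
eval_report <- function(scores, labels, model_name = "model", B = 1000L,
                        target_sensitivity = 0.65, seed = 1L) {
  scores <- as.matrix(scores); labels <- as.matrix(labels)
  targets <- colnames(scores)
  labels <- labels[, targets, drop = FALSE]
  rows <- lapply(targets, function(tg) {
    y <- labels[, tg]; s <- scores[, tg]
    if (length(unique(y)) < 2) {
      return(data.frame(model = model_name, target = tg, prevalence = mean(y),
                        auroc = NA, ci_low = NA, ci_high = NA,
                        sensitivity = NA, specificity = NA, threshold = NA))
    }
    ci <- bootstrap_ci(s, y, B = B, seed = seed)
    op <- operating_point(s, y, target_sensitivity)
    data.frame(model = model_name, target = tg, prevalence = mean(y),
               auroc = auroc(s, y), ci_low = ci[["low"]],
               ci_high = ci[["high"]], sensitivity = op$sensitivity,
               specificity = op$specificity, threshold = op$threshold)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("eval_report", "data.frame")
  out
}

#' Compare a network report with a baseline report
#'
#' @param network,baseline `eval_report` data.frames over the same targets.
#' @param ablation optional output of [ablation_series()] to serialize as
#'   curve data.
#' @return list with `comparison` (per-target AUROC delta, network minus
#'   baseline) and `ablation_curve` (long data.frame of
#'   n_targets/target/auroc rows, `NULL` when no ablation given).
#' @export
compare_models <- function(network, baseline, ablation = NULL) {
  if (!setequal(network$target, baseline$target))
    stop("reports cover different target sets")
  b <- baseline[match(network$target, baseline$target), ]
  comparison <- data.frame(target = network$target,
                           auroc_network = network$auroc,
                           auroc_baseline = b$auroc,
                           delta = network$auroc - b$auroc)
  curve <- NULL
  if (!is.null(ablation)) {
    curve <- do.call(rbind, lapply(ablation, function(st) {
      data.frame(n_targets = st$n_targets,
                 target = names(st$test_auroc),
                 auroc = as.numeric(st$test_auroc))
    }))
    rownames(curve) <- NULL
  }
  list(comparison = comparison, ablation_curve = curve)
}
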
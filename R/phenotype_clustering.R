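# Phenotype discovery: k-means on the network's first-FC-layer embeddings
# of ARDS patients, 2-D principal-component projection, and per-cluster
# target incidence tables.

#' Extract penultimate embeddings for a set of patients
#'
#' One `fc1_dim`-dimensional vector per patient: the activation of the first
#' fully connected layer, the network's compressed patient representation.
#'
#' @param model a `trained_mt_model`.
#' @param tensors list of `feature_tensor` (typically the ARDS-code-positive
#'   subset) or a stacked array.
#' @return matrix (patients x fc1_dim) with patient ids as row names.
#' @export
extract_embeddings <- function(model, tensors) {
  if (!inherits(model, "trained_mt_model")) stop("invalid state: untrained model")
  X <- if (is.list(tensors)) tensor_stack(tensors) else tensors
  E <- mt_forward(X, model)$penultimate_embedding
  rownames(E) <- dimnames(X)[[1]]
  E
}

#' Project embeddings onto their first two principal components
#'
#' Mean-centered PCA; each component's sign is fixed so that its
#' largest-magnitude loading is positive, making the projection
#' reproducible. Rank-deficient inputs degrade gracefully (second
#' coordinate 0 with a warning).
#'
#' @param embeddings numeric matrix (patients x dims), at least 3 rows.
#' @return list with `coords` (patients x 2), `explained_variance`
#'   (length-2 proportions), `rotation`.
#' @export
project_2d <- function(embeddings) {
  embeddings <- as.matrix(embeddings)
  if (nrow(embeddings) < 3) stop("need at least 3 patients")
  pc <- stats::prcomp(embeddings, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  ctr <- sweep(embeddings, 2, pc$center)
  coords <- ctr %*% rot
  ev <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  if (k < 2L || pc$sdev[2] < 1e-12 * pc$sdev[1]) {
    warning("degenerate projection: rank < 2, second coordinate set to 0")
    coords <- cbind(coords[, 1, drop = FALSE], 0)
    ev <- c(ev[1], 0)
  }
  colnames(coords) <- c("PC1", "PC2")
  list(coords = coords, explained_variance = ev, rotation = rot)
}

#' Cluster embeddings into k groups labeled by decreasing mortality
#'
#' k-means (k-means++-style multi-restart seeding via `nstart`) with a fixed
#' seed; clusters are relabeled `A`, `B`, `C`, ... in decreasing mortality
#' so the labels carry clinical meaning.
#'
#' @param embeddings numeric matrix (patients x dims).
#' @param mortality 0/1 vector (in-hospital death per patient) used only
#'   for the relabeling convention; `NULL` keeps size ordering.
#' @param k number of clusters (default 3).
#' @param seed integer seed.
#' @param nstart k-means restarts (default 10).
#' @return factor of cluster labels, plus attributes `centers` and
#'   `silhouette` (mean silhouette width diagnostic).
#' @export
cluster_embeddings <- function(embeddings, mortality = NULL, k = 3L,
                               seed = 1L, nstart = 10L) {
  embeddings <- as.matrix(embeddings)
  n <- nrow(embeddings)
  if (n < k) stop("fewer points than clusters")
  set.seed(seed)
  n_distinct <- nrow(unique(embeddings))
  k_eff <- min(k, n_distinct)
  if (k_eff < k)
    warning("fewer distinct points than clusters; using ", k_eff, " clusters")
  km <- suppressWarnings(
    stats::kmeans(embeddings, centers = k_eff, nstart = nstart,
                  iter.max = 100))
  ord <- if (!is.null(mortality)) {
    rate <- vapply(seq_len(k_eff), function(j) {
      if (any(km$cluster == j)) mean(mortality[km$cluster == j]) else -Inf
    }, numeric(1))
    order(rate, decreasing = TRUE)
  } else {
    order(km$size, decreasing = TRUE)
  }
  relabel <- match(km$cluster, ord)
  lab <- factor(LETTERS[relabel], levels = LETTERS[seq_len(k_eff)])
  names(lab) <- rownames(embeddings)
  attr(lab, "centers") <- km$centers[ord, , drop = FALSE]
  attr(lab, "silhouette") <- .mean_silhouette(embeddings, relabel, k_eff)
  lab
}

# Mean silhouette width (diagnostic only; emitted, never used for model
# selection).
.mean_silhouette <- function(x, cl, k) {
  if (k < 2 || nrow(x) > 2000) return(NA_real_)
  d <- as.matrix(stats::dist(x))
  s <- vapply(seq_len(nrow(x)), function(i) {
    own <- cl == cl[i]; own[i] <- FALSE
    a <- if (any(own)) mean(d[i, own]) else 0
    b <- min(vapply(setdiff(seq_len(k), cl[i]), function(j) {
      if (any(cl == j)) mean(d[i, cl == j]) else Inf
    }, numeric(1)))
    if (is.finite(b) && max(a, b) > 0) (b - a) / max(a, b) else 0
  }, numeric(1))
  mean(s)
}

#' Per-cluster incidence table for the 13 targets
#'
#' @param assignments factor of cluster labels (named by patient id).
#' @param labels label data.frame from [cohort_labels()] covering at least
#'   the assigned patients.
#' @return class `cluster_report`: list with `incidence` (clusters x
#'   targets incidence data.frame, plus `size` and `mortality`), and
#'   `population` (the pooled incidence vector).
#' @export
incidence_table <- function(assignments, labels) {
  ids <- names(assignments)
  if (is.null(ids)) stop("assignments must be named by patient id")
  lab <- labels[match(ids, labels$patient_id), , drop = FALSE]
  if (anyNA(lab$patient_id)) stop("assignments cover patients absent from labels")
  tg <- label_names()
  clusters <- levels(assignments)
  inc <- t(vapply(clusters, function(cl) {
    sub <- lab[assignments == cl, tg, drop = FALSE]
    colMeans(as.matrix(sub))
  }, numeric(length(tg))))
  out <- data.frame(cluster = clusters,
                    size = as.integer(table(assignments)[clusters]),
                    inc, check.names = FALSE)
  out$mortality <- out$death_12
  pop <- colMeans(as.matrix(lab[, tg]))
  structure(list(incidence = out, population = pop), class = "cluster_report")
}

#' Export clustering artifacts (assignments, incidence, 2-D coordinates)
#'
#' @param assignments factor from [cluster_embeddings()].
#' @param report a `cluster_report`.
#' @param coords 2-D coordinates from [project_2d()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
export_clustering <- function(assignments, report, coords, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(patient_id = names(assignments),
                              cluster = as.character(assignments)),
                   file.path(dir, "cluster_assignments.csv"),
                   row.names = FALSE)
  utils::write.table(report$incidence, file.path(dir, "cluster_incidence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(data.frame(patient_id = rownames(coords$coords),
                              coords$coords),
                   file.path(dir, "embedding_coords.csv"), row.names = FALSE)
  invisible(dir)
}
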
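#' PCA of normalized post-stimulus speed traces
#'
#' Mean-centered principal component analysis over the 1 s (100-bin)
#' post-stimulus window of the baseline-subtracted speed traces, retaining
#' the first `n_components` components; the exploratory, data-driven
#' counterpart of the threshold classifier.
#'
#' @param traces A [extract_trials()] result (valid trials are used), or a
#'   numeric matrix (trials x bins) of normalized post-stimulus speed.
#' @param n_components Components retained (default 3).
#' @return Object of class `response_embedding`: `scores` (trials x
#'   components), `explained` (variance fractions, non-increasing),
#'   `rotation`, `center`, `trial` (source trial indices).
#' @export
fit_response_pca <- function(traces, n_components = 3L) {
  if (inherits(traces, "trial_traces")) {
    keep <- which(traces$valid)
    X <- traces$normalized[keep, traces$time_grid >= 0, drop = FALSE]
    trial <- traces$trial[keep]
  } else {
    X <- as.matrix(traces)
    trial <- seq_len(nrow(X))
  }
  if (nrow(X) < n_components + 1L)
    stop(sprintf("need more than %d valid trials for %d components",
                 n_components, n_components), call. = FALSE)
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$x))
  tot <- sum(p$sdev^2)
  expl <- if (tot > 0) (p$sdev^2 / tot)[seq_len(k)] else rep(0, k)
  structure(list(scores = p$x[, seq_len(k), drop = FALSE],
                 explained = expl,
                 rotation = p$rotation[, seq_len(k), drop = FALSE],
                 center = p$center, trial = trial),
            class = "response_embedding")
}

#' @export
print.response_embedding <- function(x, ...) {
  cat(sprintf("<response_embedding> %d trials, %d PCs explaining %.1f%% variance\n",
              nrow(x$scores), ncol(x$scores), 100 * sum(x$explained)))
  invisible(x)
}

#' Agglomerative clustering of trial embeddings
#'
#' Ward-linkage hierarchical clustering (Euclidean distance) in the
#' principal-component space, cut at `k` clusters. Deterministic on
#' identical input.
#'
#' @param embedding A [fit_response_pca()] result.
#' @param k Number of clusters (default 4, matching the four response
#'   types; must be >= 2 and <= number of trials).
#' @return List of class `trial_clustering`: `assignments` (integer vector),
#'   `tree` (an `hclust`), `k`, `trial`.
#' @export
cluster_trials <- function(embedding, k = 4L) {
  n <- nrow(embedding$scores)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop("k exceeds the number of trials", call. = FALSE)
  h <- stats::hclust(stats::dist(embedding$scores), method = "ward.D2")
  structure(list(assignments = stats::cutree(h, k = k), tree = h, k = k,
                 trial = embedding$trial),
            class = "trial_clustering")
}

#' Compare cluster labels with threshold-classifier labels
#'
#' Cross-tabulates the two labelings and reports the adjusted Rand index
#' (chance-corrected agreement in [-1, 1]; 1 for identical partitions, ~0
#' for independent ones).
#'
#' @param cluster_labels Vector of cluster assignments.
#' @param threshold_labels Vector of classifier labels for the same trials.
#' @return List: `table` (contingency), `agreement` (adjusted Rand index).
#' @export
compare_labelings <- function(cluster_labels, threshold_labels) {
  if (length(cluster_labels) != length(threshold_labels))
    stop("labelings refer to different trial sets", call. = FALSE)
  list(table = table(threshold = threshold_labels, cluster = cluster_labels),
       agreement = mclust::adjustedRandIndex(cluster_labels, threshold_labels))
}

#' Export a clustering dendrogram as Newick text
#'
#' @param clustering A [cluster_trials()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_dendrogram <- function(clustering, path) {
  phy <- ape::as.phylo(clustering$tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Export an embedding as a tidy table
#'
#' @param embedding A [fit_response_pca()] result.
#' @param clustering Optional [cluster_trials()] result for the same trials.
#' @return data.frame `trial, pc1..pcK[, cluster]`.
#' @export
embedding_to_table <- function(embedding, clustering = NULL) {
  df <- data.frame(trial = embedding$trial)
  for (j in seq_len(ncol(embedding$scores)))
    df[[paste0("pc", j)]] <- embedding$scores[, j]
  if (!is.null(clustering)) df$cluster <- clustering$assignments
  df
}
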
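#' Representative signal: cluster member nearest the centroid
#'
#' Returns the single member curve whose PC-score Euclidean distance to its
#' own cluster centroid is minimal — the cluster "core" signal. Ties break
#' toward the lowest row index.
#'
#' @param model a `cluster_model` from [select_n_and_fit()].
#' @param cm the working [curve_matrix()] the clustering derives from.
#' @param cluster_id cluster label in 1..n.
#' @param scores the PC-score matrix used for clustering (r x m, rows
#'   aligned with `model$labels`).
#' @param rows optional mapping from score rows to `cm` rows (defaults to
#'   identity; supply when excluded curves were dropped before PCA).
#' @return An object of class `representative_signal` with `cluster_id`,
#'   `curve`, `method = "centroid_nearest"`, `member_indices` (cm rows).
#' @export
representative_centroid <- function(model, cm, cluster_id, scores,
                                    rows = seq_len(nrow(scores))) {
  members <- which(model$labels == cluster_id)
  if (length(members) == 0) stop("empty cluster", call. = FALSE)
  centroid <- model$centroids[cluster_id, ]
  d <- sqrt(rowSums(sweep(scores[members, , drop = FALSE], 2, centroid)^2))
  pick <- members[which.min(d)]      # first minimum = lowest row index
  row <- rows[pick]
  structure(list(cluster_id = as.integer(cluster_id),
                 curve = cm$values[row, ], method = "centroid_nearest",
                 member_indices = row),
            class = "representative_signal")
}

#' Representative signal: mean of the members furthest from all centroids
#'
#' Scores every cluster member by the sum of its Euclidean distances, in PC
#' space, to the centroids of all clusters, selects the top
#' `ceiling(fraction * cluster_size)` scorers (at least one), and returns
#' the unweighted mean of their normalized curves. Points far from every
#' cluster core are the least mixed, so this average avoids the
#' interface signals that sit between clusters.
#'
#' @inheritParams representative_centroid
#' @param fraction fraction of the cluster to average (default 0.10).
#' @param distance `"sum_all"` (default): sum of distances to all
#'   centroids; `"own"`: distance to the member's own centroid only.
#' @return A `representative_signal` with `method = "furthest_mean"`.
#' @export
representative_furthest <- function(model, cm, cluster_id, scores,
                                    rows = seq_len(nrow(scores)),
                                    fraction = 0.10,
                                    distance = c("sum_all", "own")) {
  distance <- match.arg(distance)
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  members <- which(model$labels == cluster_id)
  if (length(members) == 0) stop("empty cluster", call. = FALSE)
  S <- scores[members, , drop = FALSE]
  if (distance == "sum_all") {
    D <- matrix(0, nrow(S), nrow(model$centroids))
    for (j in seq_len(ncol(D))) {
      D[, j] <- sqrt(rowSums(sweep(S, 2, model$centroids[j, ])^2))
    }
    score <- rowSums(D)
  } else {
    score <- sqrt(rowSums(sweep(S, 2, model$centroids[cluster_id, ])^2))
  }
  k <- max(1L, ceiling(fraction * length(members)))
  pick <- members[order(-score, members)[seq_len(k)]]
  rows_sel <- rows[pick]
  curve <- colMeans(cm$values[rows_sel, , drop = FALSE])
  structure(list(cluster_id = as.integer(cluster_id), curve = curve,
                 method = "furthest_mean", member_indices = rows_sel),
            class = "representative_signal")
}

#' @export
print.representative_signal <- function(x, ...) {
  cat(sprintf("<representative_signal> S_%d (%s), %d member(s)\n",
              x$cluster_id, x$method, length(x$member_indices)))
  invisible(x)
}

#' Extract representative signals for every cluster
#'
#' @param model a `cluster_model`.
#' @param cm the working [curve_matrix()].
#' @param scores PC-score matrix aligned with `model$labels`.
#' @param method `"furthest"` (default), `"centroid"`, or `"both"`.
#' @param rows mapping from score rows to `cm` rows.
#' @param fraction furthest-selection fraction (default 0.10).
#' @return List of `representative_signal` objects, one per cluster (for
#'   `"both"`, a list with elements `centroid` and `furthest`).
#' @export
extract_representatives <- function(model, cm, scores,
                                    method = c("furthest", "centroid", "both"),
                                    rows = seq_len(nrow(scores)),
                                    fraction = 0.10) {
  method <- match.arg(method)
  one <- function(fun, ...) {
    lapply(seq_len(model$n), function(id) fun(model, cm, id, scores,
                                              rows = rows, ...))
  }
  switch(method,
         centroid = one(representative_centroid),
         furthest = one(representative_furthest, fraction = fraction),
         both = list(centroid = one(representative_centroid),
                     furthest = one(representative_furthest,
                                    fraction = fraction)))
}
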
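#' Principal component analysis of the feature matrix
#'
#' Columns are mean-centered internally; components are ordered by
#' decreasing explained variance and scores of distinct components are
#' uncorrelated by construction.
#'
#' @param fm a `feature_matrix` or a plain numeric matrix (r x d).
#' @return An object of class `pca_model`: `components` (d x k loadings),
#'   `scores` (r x k), `explained_ratio`, `center`.
#' @export
fit_pca <- function(fm) {
  x <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  if (nrow(x) < 2) stop("PCA needs at least two rows", call. = FALSE)
  if (ncol(x) < 1) stop("PCA needs at least one column", call. = FALSE)
  total_var <- sum(apply(x, 2, stats::var))
  if (total_var <= 0) {
    stop("rank-0 input: all rows identical, nothing to decompose", call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  structure(list(components = pc$rotation, scores = pc$x,
                 explained_ratio = pc$sdev^2 / sum(pc$sdev^2),
                 center = pc$center),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d scores x %d components; top-3 explained: %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * utils::head(x$explained_ratio, 3)),
                    collapse = ", ")))
  invisible(x)
}

#' Select the number of principal components
#'
#' Primary rule: the smallest m whose cumulative explained variance ratio
#' reaches `variance_threshold` (default 0.95). The geometric knee of the
#' L-curve — the component at maximum distance from the chord joining the
#' first and last points of the cumulative curve — is also computed and
#' reported as a diagnostic; when the two disagree a message is emitted and
#' the threshold rule wins.
#'
#' @param explained_ratio nonincreasing fractions of explained variance.
#' @param variance_threshold target cumulative fraction in (0, 1].
#' @return List of class `m_selection`: `m`, `knee`, `cumulative`.
#' @export
select_m <- function(explained_ratio, variance_threshold = 0.95) {
  if (inherits(explained_ratio, "pca_model")) {
    explained_ratio <- explained_ratio$explained_ratio
  }
  if (variance_threshold <= 0 || variance_threshold > 1) {
    stop("variance_threshold must lie in (0, 1]", call. = FALSE)
  }
  cum <- cumsum(explained_ratio)
  hit <- which(cum >= variance_threshold - 1e-12)
  m <- if (length(hit)) hit[1] else length(cum)
  knee <- lcurve_knee(cum)
  if (knee != m) {
    message(sprintf("select_m: threshold rule gives m=%d, L-curve knee at %d; using the threshold",
                    m, knee))
  }
  structure(list(m = m, knee = knee, cumulative = cum), class = "m_selection")
}

# Knee of the cumulative-variance L-curve: the point with maximum
# perpendicular distance to the chord from (1, cum_1) to (J, cum_J).
lcurve_knee <- function(cum) {
  J <- length(cum)
  if (J < 3) return(1L)
  x <- seq_len(J); x0 <- 1; y0 <- cum[1]; x1 <- J; y1 <- cum[J]
  num <- abs((y1 - y0) * x - (x1 - x0) * cum + x1 * y0 - y1 * x0)
  den <- sqrt((y1 - y0)^2 + (x1 - x0)^2)
  which.max(num / den)
}

#' Mean silhouette value of a clustering
#'
#' For each point i with intra-cluster mean distance a(i) and smallest
#' mean distance to another cluster b(i), the silhouette is
#' s(i) = (b(i) - a(i)) / max(a(i), b(i)), in [-1, 1]; points in singleton
#' clusters, and degenerate points with a = b = 0, score 0. Distances are
#' Euclidean. Returns the average over all points.
#'
#' @param scores r x m matrix of coordinates (PC scores).
#' @param labels integer cluster labels, >= 2 distinct values, none empty.
#' @return Mean silhouette value in [-1, 1].
#' @export
mean_silhouette <- function(scores, labels) {
  D <- as.matrix(stats::dist(as.matrix(scores)))
  mean_silhouette_dist(D, labels)
}

# Silhouette from a precomputed distance matrix (reused across candidate
# cluster counts so the O(r^2) distances are computed once).
mean_silhouette_dist <- function(D, labels) {
  labels <- as.integer(labels)
  r <- length(labels)
  stopifnot(nrow(D) == r)
  groups <- sort(unique(labels))
  k <- length(groups)
  if (k < 2) stop("silhouette requires at least two clusters", call. = FALSE)
  ind <- matrix(0, r, k)
  ind[cbind(seq_len(r), match(labels, groups))] <- 1
  counts <- colSums(ind)
  if (any(counts == 0)) stop("empty cluster", call. = FALSE)
  S <- D %*% ind                                   # r x k summed distances
  own <- match(labels, groups)
  a <- S[cbind(seq_len(r), own)] / pmax(counts[own] - 1, 1)
  Sother <- S / rep(counts, each = r)
  Sother[cbind(seq_len(r), own)] <- Inf
  b <- apply(Sother, 1, min)
  denom <- pmax(a, b)
  s <- ifelse(denom > 0, (b - a) / denom, 0)
  s[counts[own] == 1] <- 0                         # singleton convention
  mean(s)
}

# k-means++-style greedy seeding: first center drawn uniformly, each
# subsequent center drawn with probability proportional to the squared
# distance to the nearest chosen center.
kmeanspp_init <- function(X, k) {
  r <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  i <- sample.int(r, 1L)
  centers[1, ] <- X[i, ]
  if (k > 1) {
    d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
    for (j in 2:k) {
      if (sum(d2) <= 0) i <- sample.int(r, 1L)
      else i <- sample.int(r, 1L, prob = d2)
      centers[j, ] <- X[i, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
    }
  }
  centers
}

# Lloyd iterations from given initial centers. The within-cluster
# sum-of-squares objective is asserted nonincreasing at every iteration.
# Returns NULL if a cluster empties.
kmeans_lloyd <- function(X, centers, max_iter = 300, tol = 1e-6) {
  r <- nrow(X); k <- nrow(centers)
  xs <- rowSums(X^2)
  obj_prev <- Inf
  labels <- integer(r)
  for (it in seq_len(max_iter)) {
    d2 <- outer(xs, rowSums(centers^2), "+") - 2 * X %*% t(centers)
    labels <- max.col(-d2, ties.method = "first")
    obj <- sum(d2[cbind(seq_len(r), labels)])
    obj <- max(obj, 0)
    if (obj > obj_prev + 1e-8 * (1 + obj_prev)) {
      stop("internal error: k-means objective increased", call. = FALSE)
    }
    newc <- matrix(0, k, ncol(X))
    for (j in seq_len(k)) {
      members <- labels == j
      if (!any(members)) return(NULL)
      newc[j, ] <- colMeans(X[members, , drop = FALSE])
    }
    shift <- sqrt(max(rowSums((newc - centers)^2)))
    centers <- newc
    if (shift < tol || abs(obj_prev - obj) == 0) break
    obj_prev <- obj
  }
  d2 <- outer(xs, rowSums(centers^2), "+") - 2 * X %*% t(centers)
  labels <- max.col(-d2, ties.method = "first")
  inertia <- max(sum(d2[cbind(seq_len(r), labels)]), 0)
  list(labels = labels, centers = centers, inertia = inertia,
       iterations = it)
}

# Best of `restarts` seeded Lloyd runs; NULL if every restart emptied a
# cluster.
kmeans_restarts <- function(X, k, restarts = 20) {
  best <- NULL
  for (rs in seq_len(restarts)) {
    fit <- kmeans_lloyd(X, kmeanspp_init(X, k))
    if (is.null(fit)) next
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  best
}

#' Select the number of clusters by the silhouette criterion and fit k-means
#'
#' For every candidate cluster count n the PC scores are clustered by
#' k-means (Lloyd iterations, k-means++-style seeding, `restarts` restarts,
#' best within-cluster sum of squares kept) and the mean silhouette of the
#' best run is recorded. The selected n maximizes the mean silhouette; ties
#' resolve toward the smaller n (parsimony). Deterministic for a fixed
#' `seed`.
#'
#' @param scores r x m matrix of retained PC scores.
#' @param n_candidates candidate cluster counts (default 2:8).
#' @param seed integer RNG seed.
#' @param restarts k-means restarts per candidate (default 20).
#' @return An object of class `cluster_model`: `n`, `labels` (length r),
#'   `centroids` (n x m), `mean_silhouette` (named vector over candidates),
#'   `seed`, `n_candidates`.
#' @export
select_n_and_fit <- function(scores, n_candidates = 2:8, seed = 1L,
                             restarts = 20) {
  scores <- as.matrix(scores)
  r <- nrow(scores)
  n_candidates <- sort(unique(as.integer(n_candidates)))
  if (any(n_candidates < 2)) {
    stop("candidate cluster counts must be >= 2", call. = FALSE)
  }
  if (r <= max(n_candidates)) {
    stop("need more points than the largest candidate cluster count",
         call. = FALSE)
  }
  D <- as.matrix(stats::dist(scores))
  fits <- list()
  sil <- rep(NA_real_, length(n_candidates))
  names(sil) <- n_candidates
  local_seed(seed, {
    for (j in seq_along(n_candidates)) {
      n <- n_candidates[j]
      fit <- kmeans_restarts(scores, n, restarts = restarts)
      if (is.null(fit)) {
        message(sprintf("select_n_and_fit: candidate n=%d skipped (empty cluster in all restarts)", n))
        next
      }
      fits[[j]] <- fit
      sil[j] <- mean_silhouette_dist(D, fit$labels)
    }
  })
  if (all(is.na(sil))) stop("no candidate cluster count succeeded", call. = FALSE)
  best_j <- which(sil == max(sil, na.rm = TRUE))[1]  # ties -> smaller n
  fit <- fits[[best_j]]
  structure(list(n = n_candidates[best_j], labels = fit$labels,
                 centroids = fit$centers, mean_silhouette = sil,
                 inertia = fit$inertia, seed = as.integer(seed),
                 n_candidates = n_candidates),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> n=%d clusters selected from {%s}\n", x$n,
              paste(x$n_candidates, collapse = ",")))
  tab <- data.frame(n = x$n_candidates,
                    mean_silhouette = round(x$mean_silhouette, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Place cluster labels on the scan grid
#'
#' @param labels integer labels of the clustered (non-excluded) curves, in
#'   curve order.
#' @param grid a [scan_grid()].
#' @param excluded integer indices (1-based, in raster curve order) of
#'   pixels excluded from clustering; they receive label 0.
#' @return A [label_map()].
#' @export
labels_to_map <- function(labels, grid, excluded = integer(0)) {
  stopifnot(inherits(grid, "scan_grid"))
  r <- grid$ny * grid$nx
  excluded <- as.integer(excluded)
  if (length(labels) + length(excluded) != r) {
    stop(sprintf("label count %d + excluded %d does not match grid size %d",
                 length(labels), length(excluded), r), call. = FALSE)
  }
  full <- integer(r)
  keep <- setdiff(seq_len(r), excluded)
  full[keep] <- as.integer(labels)
  px <- index_to_pixel(grid)
  mat <- matrix(0L, grid$ny, grid$nx)
  mat[cbind(px[, 1] + 1L, px[, 2] + 1L)] <- full
  label_map(mat, grid)
}
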
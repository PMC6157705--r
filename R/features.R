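#' Smoothed derivatives of curves with respect to log q
#'
#' Estimates first and second derivatives of every curve by local
#' least-squares polynomial smoothing (Savitzky-Golay style) in the
#' variable u = log q, the natural axis for log-resampled scattering
#' curves where slope features encode power-law exponents. Interior points
#' use a centered window of `window` bins; endpoints use shrinking
#' one-sided windows so every bin gets an estimate. The fit uses the
#' actual (possibly non-uniform) log-q offsets, so no grid uniformity is
#' assumed.
#'
#' @param cm a [curve_matrix()] (or plain matrix plus `q`).
#' @param window odd integer window length, `3 <= window <= c`.
#' @param polyorder polynomial order, `polyorder < window` (>= 2 for
#'   second derivatives).
#' @param q q grid when `cm` is a plain matrix.
#' @return List with matrices `d1` and `d2` (same shape as the input
#'   values): dI/du and d2I/du2 at every bin.
#' @export
smooth_and_differentiate <- function(cm, window = 5, polyorder = 2, q = NULL) {
  if (inherits(cm, "curve_matrix")) {
    values <- cm$values
    q <- cm$q
  } else {
    values <- as.matrix(cm)
    if (is.null(q)) stop("q grid required for a plain matrix", call. = FALSE)
  }
  c_out <- ncol(values)
  if (window %% 2 != 1 || window < 3) {
    stop("window must be an odd integer >= 3", call. = FALSE)
  }
  if (window > c_out) {
    stop("derivative window larger than the curve", call. = FALSE)
  }
  if (polyorder >= window) stop("polyorder must be < window", call. = FALSE)
  op <- deriv_operators(log(q), window, polyorder)
  list(d1 = values %*% t(op$D1), d2 = values %*% t(op$D2))
}

# c x c linear operators mapping a sampled function on grid u to its first
# and second derivative estimates, by local polynomial least squares.
deriv_operators <- function(u, window, polyorder) {
  c_out <- length(u)
  h <- (window - 1L) %/% 2L
  D1 <- matrix(0, c_out, c_out)
  D2 <- matrix(0, c_out, c_out)
  for (i in seq_len(c_out)) {
    idx <- max(1L, i - h):min(c_out, i + h)
    p <- min(polyorder, length(idx) - 1L)
    X <- outer(u[idx] - u[i], 0:p, "^")
    W <- solve(crossprod(X), t(X))   # (p+1) x |idx| pseudoinverse
    if (p >= 1) D1[i, idx] <- W[2, ]
    if (p >= 2) D2[i, idx] <- 2 * W[3, ]
  }
  list(D1 = D1, D2 = D2)
}

# Sign-change bins of one derivative vector. A crossing between the
# nearest flanking nonzero samples i < k with opposite signs is kept when
# the derivative magnitude within `flank_width` bins of the crossing
# reaches `floor_abs` (samples adjacent to a genuine zero are themselves
# near zero, so the guard inspects a neighborhood), and is assigned to the
# bin nearer the linearly interpolated zero position.
sign_change_bins <- function(d, floor_abs, flank_width = 5L) {
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) < 2) return(integer(0))
  out <- integer(0)
  for (j in seq_len(length(nz) - 1L)) {
    i <- nz[j]; k <- nz[j + 1L]
    if (s[i] * s[k] != -1) next
    flank <- max(abs(d[max(1L, i - flank_width):min(length(d), k + flank_width)]))
    if (flank < floor_abs) next
    if (k == i + 1L) {
      t <- abs(d[i]) / (abs(d[i]) + abs(d[k]))
      out <- c(out, if (t <= 0.5) i else k)
    } else {
      # exact zeros between the flanks: take the middle zero bin
      out <- c(out, as.integer(round((i + k) / 2)))
    }
  }
  out
}

#' Detect inflection-point bins of one curve
#'
#' An inflection bin is one where the first or the second derivative of
#' I(log q) changes sign. Sign changes whose flanking derivative magnitudes
#' fall below `prominence_floor` times the row's maximum absolute derivative
#' are discarded as noise. A bin where both derivatives change sign counts
#' once. Curves with no inflections (e.g. pure power laws) yield an empty
#' set.
#'
#' @param d1,d2 derivative vectors of one curve (from
#'   [smooth_and_differentiate()]).
#' @param prominence_floor fraction of the row maximum absolute derivative
#'   below which sign changes are ignored (default 0.05). The magnitude of
#'   a sign change is taken as the largest derivative magnitude within
#'   `flank_width` bins of the crossing.
#' @param flank_width neighborhood half-width (bins) for the prominence
#'   guard.
#' @return Sorted integer vector of bin indices (possibly empty).
#' @export
find_inflections <- function(d1, d2, prominence_floor = 0.05,
                             flank_width = 5L) {
  b1 <- sign_change_bins(d1, prominence_floor * max(abs(d1)), flank_width)
  b2 <- sign_change_bins(d2, prominence_floor * max(abs(d2)), flank_width)
  sort(unique(c(b1, b2)))
}

#' Assemble the sparse feature matrix M2
#'
#' The feature q positions are the union, over all curves, of the detected
#' inflection bins, in increasing q order. Entry (i, j) is curve i's
#' intensity at feature bin j — drawn verbatim from the curve matrix, never
#' re-interpolated — if curve i detected that bin, and 0 otherwise. Curves
#' with no detected features are retained as all-zero rows.
#'
#' @param cm the [curve_matrix()] the detections were made on.
#' @param inflections list of per-row inflection index vectors (length r).
#' @return An object of class `feature_matrix` with elements `values`
#'   (r x d), `feature_q`, `feature_bins`, `detected` (r x d logical) and
#'   `source_q` (the full working grid).
#' @export
build_feature_matrix <- function(cm, inflections) {
  stopifnot(inherits(cm, "curve_matrix"))
  r <- nrow(cm$values)
  if (length(inflections) != r) {
    stop("one inflection set per curve is required", call. = FALSE)
  }
  bins <- sort(unique(unlist(inflections)))
  if (length(bins) == 0) {
    stop("no features: no curve has a detected inflection point", call. = FALSE)
  }
  d <- length(bins)
  if (d >= ncol(cm$values)) {
    warning("feature count d is not smaller than the number of q bins; ",
            "consider raising prominence_floor", call. = FALSE)
  }
  detected <- matrix(FALSE, r, d)
  col_of <- integer(max(bins))
  col_of[bins] <- seq_len(d)
  for (i in seq_len(r)) {
    if (length(inflections[[i]]) > 0) {
      detected[i, col_of[inflections[[i]]]] <- TRUE
    }
  }
  values <- cm$values[, bins, drop = FALSE] * detected
  structure(list(values = values, feature_q = cm$q[bins], feature_bins = bins,
                 detected = detected, source_q = cm$q),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d curves x %d features (of %d q bins), %d featureless rows\n",
              nrow(x$values), ncol(x$values), length(x$source_q),
              sum(rowSums(x$detected) == 0)))
  invisible(x)
}

#' Full feature-extraction step
#'
#' Runs [smooth_and_differentiate()] and [find_inflections()] on every
#' non-excluded curve and assembles the feature matrix. Excluded rows get
#' empty inflection sets (all-zero feature rows).
#'
#' @param cm a preprocessed [curve_matrix()].
#' @param window,polyorder see [smooth_and_differentiate()].
#' @param prominence_floor see [find_inflections()].
#' @return A `feature_matrix`.
#' @export
detect_features <- function(cm, window = 5, polyorder = 2,
                            prominence_floor = 0.05) {
  stopifnot(inherits(cm, "curve_matrix"))
  dv <- smooth_and_differentiate(cm, window = window, polyorder = polyorder)
  r <- nrow(cm$values)
  infl <- vector("list", r)
  for (i in seq_len(r)) {
    infl[[i]] <- if (cm$excluded[i]) integer(0) else {
      find_inflections(dv$d1[i, ], dv$d2[i, ], prominence_floor)
    }
  }
  build_feature_matrix(cm, infl)
}
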
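#' Pearson correlation coefficient
#'
#' rho = cov(x, y) / (sigma_x * sigma_y), sample (n-1) convention. Inputs
#' with zero variance have no defined correlation; `NA` is returned with a
#' warning (never 0, which would mean "uncorrelated").
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Correlation in [-1, 1], or `NA` for zero-variance input.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  xc <- x - mean(x)
  yc <- y - mean(y)
  sx2 <- sum(xc^2)
  sy2 <- sum(yc^2)
  if (sx2 == 0 || sy2 == 0) {
    warning("zero-variance input: correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  r <- sum(xc * yc) / sqrt(sx2 * sy2)   # the (n-1) factors cancel
  min(1, max(-1, r))
}

#' Per-pixel Pearson correlation maps against representative signals
#'
#' Correlates every curve of the working matrix with each representative
#' signal S_k, giving n maps of ny x nx correlation coefficients — each
#' pixel gets one coefficient per cluster. Excluded and zero-variance
#' curves yield `NA`.
#'
#' @param cm the working [curve_matrix()] (normalized, resampled curves).
#' @param reps list of `representative_signal` objects on the same q grid.
#' @param grid a [scan_grid()]; defaults to the one bound to `cm`.
#' @return An object of class `corr_maps`: `rho` (ny x nx x n array),
#'   `cluster_ids`, `grid`, `thresholded` (NULL until
#'   [threshold_median()]).
#' @export
correlation_maps <- function(cm, reps, grid = cm$grid) {
  stopifnot(inherits(cm, "curve_matrix"))
  if (length(reps) == 0) stop("no representative signals", call. = FALSE)
  if (is.null(grid)) stop("no scan grid bound to the curves", call. = FALSE)
  if (grid$ny * grid$nx != nrow(cm$values)) {
    stop("grid size does not match the number of curves", call. = FALSE)
  }
  c_out <- ncol(cm$values)
  bad_len <- vapply(reps, function(rp) length(rp$curve) != c_out, logical(1))
  if (any(bad_len)) stop("representative curves not on the working q grid",
                         call. = FALSE)

  X <- cm$values - rowMeans(cm$values)
  xn <- sqrt(rowSums(X^2))
  Y <- vapply(reps, function(rp) {
    yc <- rp$curve - mean(rp$curve)
    s <- sqrt(sum(yc^2))
    if (s == 0) rep(NA_real_, c_out) else yc / s
  }, numeric(c_out))                           # c x n
  rho_flat <- (X / ifelse(xn == 0, NA, xn)) %*% Y
  rho_flat[cm$excluded, ] <- NA
  rho_flat <- pmin(pmax(rho_flat, -1), 1)

  n <- length(reps)
  px <- index_to_pixel(grid)
  rho <- array(NA_real_, dim = c(grid$ny, grid$nx, n))
  for (k in seq_len(n)) {
    m <- matrix(NA_real_, grid$ny, grid$nx)
    m[cbind(px[, 1] + 1L, px[, 2] + 1L)] <- rho_flat[, k]
    rho[, , k] <- m
  }
  ids <- vapply(reps, function(rp) rp$cluster_id, integer(1))
  structure(list(rho = rho, cluster_ids = ids, grid = grid,
                 thresholded = NULL),
            class = "corr_maps")
}

#' @export
print.corr_maps <- function(x, ...) {
  cat(sprintf("<corr_maps> %d maps of %dx%d pixels%s\n", dim(x$rho)[3],
              x$grid$ny, x$grid$nx,
              if (is.null(x$thresholded)) "" else " (thresholded)"))
  invisible(x)
}

#' Median thresholding of correlation maps
#'
#' For graphical use, coefficients below the median of the whole image are
#' set to zero so that weakly correlated regions do not overlap. Each
#' cluster's map is thresholded at its own median over all finite pixels
#' (`scope = "per_map"`, default); `scope = "global"` uses one median
#' across all n maps. Values equal to the median are retained. Applying the
#' threshold twice changes nothing.
#'
#' @param maps a `corr_maps` object.
#' @param scope `"per_map"` or `"global"`.
#' @return The `corr_maps` with the `thresholded` array filled in.
#' @export
threshold_median <- function(maps, scope = c("per_map", "global")) {
  stopifnot(inherits(maps, "corr_maps"))
  scope <- match.arg(scope)
  src <- if (is.null(maps$thresholded)) maps$rho else maps$thresholded
  n <- dim(src)[3]
  out <- src
  if (scope == "global") {
    if (all(!is.finite(src))) stop("all correlation values missing", call. = FALSE)
    med <- stats::median(src[is.finite(src)])
    out[is.finite(out) & out < med] <- 0
  } else {
    for (k in seq_len(n)) {
      m <- src[, , k]
      if (all(!is.finite(m))) {
        stop(sprintf("correlation map %d is all-missing", k), call. = FALSE)
      }
      med <- stats::median(m[is.finite(m)])
      m[is.finite(m) & m < med] <- 0
      out[, , k] <- m
    }
  }
  maps$thresholded <- out
  maps
}

#' Compose three thresholded correlation maps into an RGB image
#'
#' Assigns one cluster map to each of the red, green and blue channels.
#' Negative values are clipped to zero, each channel is divided by its own
#' maximum (channel-wise max normalization, so spatial structure survives
#' weak absolute correlations), and missing pixels render black. Color
#' mixtures then show pixels correlated with several representatives.
#'
#' @param maps a `corr_maps`, already thresholded via [threshold_median()]
#'   (if not, thresholding is applied first).
#' @param channels integer vector of 3 distinct cluster ids for (R, G, B).
#' @return `ny x nx x 3` numeric array with values in [0, 1].
#' @export
compose_rgb <- function(maps, channels = maps$cluster_ids[1:3]) {
  stopifnot(inherits(maps, "corr_maps"))
  if (dim(maps$rho)[3] < 3) {
    stop("fewer than 3 cluster maps available; render single maps in grayscale instead",
         call. = FALSE)
  }
  channels <- as.integer(channels)
  if (length(channels) != 3 || anyDuplicated(channels)) {
    stop("exactly 3 distinct cluster ids are required", call. = FALSE)
  }
  idx <- match(channels, maps$cluster_ids)
  if (any(is.na(idx))) stop("unknown cluster id in channel assignment", call. = FALSE)
  if (is.null(maps$thresholded)) maps <- threshold_median(maps)
  img <- array(0, dim = c(maps$grid$ny, maps$grid$nx, 3))
  all_zero <- TRUE
  for (ch in 1:3) {
    m <- maps$thresholded[, , idx[ch]]
    m[!is.finite(m)] <- 0
    m[m < 0] <- 0
    mx <- max(m)
    if (mx > 0) {
      m <- m / mx
      all_zero <- FALSE
    }
    img[, , ch] <- m
  }
  if (all_zero) warning("all thresholded maps are zero: black image", call. = FALSE)
  img
}

#' Write correlation maps to disk
#'
#' Emits one grayscale PNG per cluster map (correlations linearly mapped
#' from [-1, 1] to [0, 1]), a CSV of per-pixel coefficients
#' (`row, col, rho_1..rho_n`), and — when at least three clusters exist —
#' the RGB composite PNG.
#'
#' @param maps a `corr_maps`.
#' @param dir output directory.
#' @param channels RGB channel assignment (default first three cluster
#'   ids).
#' @return Named character vector of the files written.
#' @export
write_correlation_maps <- function(maps, dir,
                                   channels = maps$cluster_ids[1:3]) {
  stopifnot(inherits(maps, "corr_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(maps$rho)[3]
  files <- character(0)
  for (k in seq_len(n)) {
    m <- maps$rho[, , k]
    img <- (m + 1) / 2
    img[!is.finite(img)] <- 0
    f <- file.path(dir, sprintf("corr_S%d.png", maps$cluster_ids[k]))
    png::writePNG(pmin(pmax(img, 0), 1), f)
    files <- c(files, f)
  }
  px <- index_to_pixel(maps$grid)
  flat <- vapply(seq_len(n), function(k) {
    maps$rho[, , k][cbind(px[, 1] + 1L, px[, 2] + 1L)]
  }, numeric(nrow(px)))
  tab <- data.frame(row = px[, 1], col = px[, 2], flat)
  names(tab)[-(1:2)] <- sprintf("rho_%d", maps$cluster_ids)
  csv <- file.path(dir, "correlations.csv")
  utils::write.csv(tab, csv, row.names = FALSE, quote = FALSE)
  files <- c(files, csv)
  if (n >= 3) {
    rgb_file <- file.path(dir, "corr_rgb.png")
    png::writePNG(compose_rgb(maps, channels), rgb_file)
    files <- c(files, rgb_file)
  }
  invisible(files)
}
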
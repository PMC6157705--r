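#' Curve matrix container
#'
#' The working representation of a scan dataset: an `r x c` matrix of
#' intensities (one row per scan pixel, raster order) on a shared q grid,
#' with provenance flags recording which preprocessing steps have been
#' applied and a logical vector of excluded rows (e.g. empty curves).
#'
#' @param values r x c nonnegative matrix.
#' @param q_centers length-c strictly increasing q values (nm^-1).
#' @param grid optional [scan_grid()] bound to the rows.
#' @param normalized,resampled,background_subtracted provenance flags.
#' @param excluded logical length-r vector of rows excluded from analysis.
#' @return An object of class `curve_matrix`.
#' @export
curve_matrix <- function(values, q_centers, grid = NULL, normalized = FALSE,
                         resampled = FALSE, background_subtracted = FALSE,
                         excluded = rep(FALSE, nrow(values))) {
  values <- as.matrix(values)
  check_q_grid(q_centers)
  if (ncol(values) != length(q_centers)) {
    stop("column count must match q grid length", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("intensities must be finite", call. = FALSE)
  if (!is.null(grid) && grid$ny * grid$nx != nrow(values)) {
    stop("grid size does not match the number of curves", call. = FALSE)
  }
  structure(list(values = values, q = as.numeric(q_centers), grid = grid,
                 normalized = normalized, resampled = resampled,
                 background_subtracted = background_subtracted,
                 excluded = excluded),
            class = "curve_matrix")
}

#' @export
print.curve_matrix <- function(x, ...) {
  flags <- c(if (x$normalized) "normalized", if (x$resampled) "resampled",
             if (x$background_subtracted) "bg-subtracted")
  cat(sprintf("<curve_matrix> %d curves x %d q points [%s], %d excluded\n",
              nrow(x$values), ncol(x$values),
              if (length(flags)) paste(flags, collapse = ", ") else "raw",
              sum(x$excluded)))
  invisible(x)
}

#' Subtract a background curve
#'
#' Subtracts a measured background (e.g. the empty sample holder) from every
#' curve and clips negative residuals at zero: intensities are photon counts
#' and negative differences are noise. The number of clipped values is
#' reported via `message()`. The background must be on the identical q grid;
#' differing grids are rejected, never interpolated.
#'
#' @param cm a [curve_matrix()].
#' @param background a [scattering_curve()] or a numeric vector on the same
#'   q grid.
#' @return The background-subtracted [curve_matrix()]; rows that become
#'   all-zero are flagged excluded.
#' @export
subtract_background <- function(cm, background) {
  stopifnot(inherits(cm, "curve_matrix"))
  if (inherits(background, "scattering_curve")) {
    if (!isTRUE(all.equal(background$q, cm$q, tolerance = 1e-12))) {
      stop("background q grid does not match the curve matrix", call. = FALSE)
    }
    bg <- background$intensity
  } else {
    bg <- as.numeric(background)
  }
  if (length(bg) != ncol(cm$values)) {
    stop("background length does not match the q grid", call. = FALSE)
  }
  out <- sweep(cm$values, 2, bg, "-")
  n_clip <- sum(out < 0)
  if (n_clip > 0) {
    message(sprintf("subtract_background: clipped %d negative values to 0",
                    n_clip))
    out[out < 0] <- 0
  }
  empty <- rowSums(out) == 0
  if (any(empty & !cm$excluded)) {
    message(sprintf("subtract_background: %d curves became empty and are excluded",
                    sum(empty & !cm$excluded)))
  }
  curve_matrix(out, cm$q, grid = cm$grid, normalized = cm$normalized,
               resampled = cm$resampled, background_subtracted = TRUE,
               excluded = cm$excluded | empty)
}

#' Normalize every curve by its mean intensity
#'
#' Divides each curve by its intensity averaged over the measured q range,
#' bringing all curves to the same order of magnitude so that
#' classification responds to curve shape, not to thickness or flux
#' variations. All-zero rows cannot be normalized; they are flagged excluded
#' (kept in maps as unassigned) and left at zero.
#'
#' @param cm a [curve_matrix()].
#' @return The normalized [curve_matrix()]; every non-excluded row has mean
#'   exactly 1 up to floating tolerance.
#' @export
normalize_mean <- function(cm) {
  stopifnot(inherits(cm, "curve_matrix"))
  m <- rowMeans(cm$values)
  zero <- m <= 0
  if (any(zero & !cm$excluded)) {
    message(sprintf("normalize_mean: %d all-zero curves excluded from clustering",
                    sum(zero & !cm$excluded)))
  }
  scale <- ifelse(zero, 1, m)
  curve_matrix(cm$values / scale, cm$q, grid = cm$grid, normalized = TRUE,
               resampled = cm$resampled,
               background_subtracted = cm$background_subtracted,
               excluded = cm$excluded | zero)
}

#' Normalize curves by per-pixel transmission
#'
#' Optional pre-step dividing each curve by its measured transmission,
#' the common normalization for scanning SAXS/WAXS mapping. Off by default
#' in the pipeline: the classifier normalizes by mean intensity instead,
#' since it compares curve shapes.
#'
#' @param cm a [curve_matrix()].
#' @param transmission numeric vector in (0, 1], one value per curve.
#' @export
normalize_transmission <- function(cm, transmission) {
  stopifnot(inherits(cm, "curve_matrix"))
  if (length(transmission) != nrow(cm$values)) {
    stop("one transmission value per curve is required", call. = FALSE)
  }
  if (any(transmission <= 0 | transmission > 1)) {
    stop("transmission values must lie in (0, 1]", call. = FALSE)
  }
  curve_matrix(cm$values / transmission, cm$q, grid = cm$grid,
               normalized = cm$normalized, resampled = cm$resampled,
               background_subtracted = cm$background_subtracted,
               excluded = cm$excluded)
}

#' Logarithmic resampling (rebinning) of the q axis
#'
#' Reduces the number of q channels by `reduction_factor` using bins whose
#' edges are uniform in log q over `[q_min, q_max]`. Each bin's value is the
#' arithmetic mean of its member intensities (averaging, not decimation, so
#' high-frequency counting noise is suppressed); the bin center is the
#' geometric mean of its edges. Bins that receive no q samples are filled by
#' linear interpolation between neighboring bins and reported via
#' `message()`.
#'
#' @param cm a [curve_matrix()] on a raw q grid (all q > 0).
#' @param reduction_factor integer >= 2; the default 10 reduces c_raw
#'   channels to `ceiling(c_raw / 10)` bins.
#' @return The resampled [curve_matrix()] with `c = ceiling(c_raw /
#'   reduction_factor)` columns.
#' @export
log_resample <- function(cm, reduction_factor = 10) {
  stopifnot(inherits(cm, "curve_matrix"))
  if (reduction_factor < 2) stop("reduction_factor must be >= 2", call. = FALSE)
  c_raw <- ncol(cm$values)
  if (c_raw < 2 * reduction_factor) {
    stop("too few q channels for the requested reduction", call. = FALSE)
  }
  if (cm$q[1] <= 0) stop("log resampling requires q > 0", call. = FALSE)
  c_out <- ceiling(c_raw / reduction_factor)
  edges <- exp(seq(log(cm$q[1]), log(cm$q[c_raw]), length.out = c_out + 1))
  centers <- sqrt(edges[-1] * edges[-(c_out + 1)])
  # member bin of each raw channel; right edge closed for the last bin
  bin <- findInterval(cm$q, edges, rightmost.closed = TRUE)
  bin[bin < 1] <- 1L
  bin[bin > c_out] <- c_out
  counts <- tabulate(bin, nbins = c_out)

  # binning as a matrix operation: A[i, j] = 1/counts[j] if channel i in bin j
  A <- matrix(0, c_raw, c_out)
  A[cbind(seq_len(c_raw), bin)] <- 1 / counts[bin]
  vals <- cm$values %*% A

  empty <- counts == 0
  if (any(empty)) {
    message(sprintf("log_resample: %d empty bins filled by interpolation",
                    sum(empty)))
    filled <- which(!empty)
    for (i in seq_len(nrow(vals))) {
      vals[i, empty] <- stats::approx(centers[filled], vals[i, filled],
                                      xout = centers[empty], rule = 2)$y
    }
  }
  curve_matrix(vals, centers, grid = cm$grid, normalized = cm$normalized,
               resampled = TRUE,
               background_subtracted = cm$background_subtracted,
               excluded = cm$excluded)
}

#' Standard preprocessing: normalize then log-resample
#'
#' Applies the pipeline's default preprocessing to a raw curve stack:
#' optional transmission normalization, optional background subtraction,
#' mean-intensity normalization (the row mean is taken over the measured,
#' i.e. raw, q range), then logarithmic resampling. Row order (the scan
#' mapping) is never permuted.
#'
#' @param q raw q grid.
#' @param intensities r x c_raw matrix.
#' @param grid optional [scan_grid()].
#' @param background optional background curve (vector or
#'   [scattering_curve()]).
#' @param transmission optional per-curve transmission values.
#' @param normalize apply mean normalization (default TRUE).
#' @param resample_factor log-rebinning factor (default 10); `NULL` or 1
#'   skips resampling.
#' @return A [curve_matrix()] (the analysis matrix M1).
#' @export
preprocess_curves <- function(q, intensities, grid = NULL, background = NULL,
                              transmission = NULL, normalize = TRUE,
                              resample_factor = 10) {
  cm <- curve_matrix(as.matrix(intensities), q, grid = grid)
  if (!is.null(transmission)) cm <- normalize_transmission(cm, transmission)
  if (!is.null(background)) cm <- subtract_background(cm, background)
  if (normalize) cm <- normalize_mean(cm)
  if (!is.null(resample_factor) && resample_factor > 1) {
    cm <- log_resample(cm, resample_factor)
  }
  cm
}
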
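#' Define a synthetic scattering phase
#'
#' A phase spectrum is a parametric model of an azimuthally integrated
#' scattering curve: a set of Gaussian Bragg lines on top of a power-law
#' continuum and a flat (incoherent/instrumental) background,
#' \deqn{I(q) = \sum_k A_k \exp(-(q-\mu_k)^2 / 2\sigma_k^2) + B q^{-p} + F.}
#' Gaussian lines provide peak-type features (first-derivative zeros) and the
#' power-law-to-flat transition provides slope-change features, the two kinds
#' of inflection the classification keys on.
#'
#' @param peaks data frame (or coercible) with columns `center` (nm^-1),
#'   `width` (Gaussian sigma, nm^-1) and `amplitude` (counts); may have zero
#'   rows.
#' @param powerlaw_exponent dimensionless exponent p >= 0.
#' @param powerlaw_amplitude amplitude B >= 0 (counts).
#' @param flat_background constant F >= 0 (counts).
#' @param name optional label used in printing and truth tables.
#' @return An object of class `phase_spectrum`.
#' @export
phase_spectrum <- function(peaks = NULL, powerlaw_exponent = 0,
                           powerlaw_amplitude = 0, flat_background = 0,
                           name = NULL) {
  if (is.null(peaks)) {
    peaks <- data.frame(center = numeric(0), width = numeric(0),
                        amplitude = numeric(0))
  }
  peaks <- as.data.frame(peaks)
  required <- c("center", "width", "amplitude")
  if (!all(required %in% names(peaks))) {
    stop("`peaks` needs columns center, width, amplitude", call. = FALSE)
  }
  peaks <- peaks[required]
  if (nrow(peaks) > 0) {
    if (any(peaks$width <= 0)) stop("peak widths must be > 0", call. = FALSE)
    if (any(peaks$amplitude < 0)) stop("peak amplitudes must be >= 0", call. = FALSE)
    if (any(peaks$center <= 0)) stop("peak centers must be positive q", call. = FALSE)
  }
  if (powerlaw_exponent < 0) stop("powerlaw_exponent must be >= 0", call. = FALSE)
  if (powerlaw_amplitude < 0) stop("powerlaw_amplitude must be >= 0", call. = FALSE)
  if (flat_background < 0) stop("flat_background must be >= 0", call. = FALSE)
  structure(
    list(peaks = peaks, powerlaw_exponent = powerlaw_exponent,
         powerlaw_amplitude = powerlaw_amplitude,
         flat_background = flat_background, name = name),
    class = "phase_spectrum")
}

#' @export
print.phase_spectrum <- function(x, ...) {
  cat("<phase_spectrum>", if (!is.null(x$name)) x$name else "", "\n")
  cat("  peaks:", nrow(x$peaks),
      " power-law: B=", x$powerlaw_amplitude, " p=", x$powerlaw_exponent,
      " flat:", x$flat_background, "\n", sep = "")
  invisible(x)
}

#' Evaluate a phase spectrum on a q grid
#'
#' @param spectrum a [phase_spectrum()].
#' @param q_grid strictly increasing positive scattering-vector magnitudes
#'   (nm^-1).
#' @return Numeric intensity vector, same length as `q_grid`.
#' @export
evaluate_phase <- function(spectrum, q_grid) {
  stopifnot(inherits(spectrum, "phase_spectrum"))
  check_q_grid(q_grid)
  intensity <- rep(spectrum$flat_background, length(q_grid))
  if (spectrum$powerlaw_amplitude > 0) {
    intensity <- intensity +
      spectrum$powerlaw_amplitude * q_grid^(-spectrum$powerlaw_exponent)
  }
  pk <- spectrum$peaks
  for (k in seq_len(nrow(pk))) {
    intensity <- intensity +
      pk$amplitude[k] * exp(-(q_grid - pk$center[k])^2 / (2 * pk$width[k]^2))
  }
  intensity
}

check_q_grid <- function(q) {
  if (!is.numeric(q) || length(q) < 1) {
    stop("q grid must be a nonempty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(q)) || any(q <= 0)) {
    stop("q grid must be finite and strictly positive", call. = FALSE)
  }
  if (any(diff(q) <= 0)) {
    stop("q grid must be strictly increasing", call. = FALSE)
  }
  invisible(q)
}

#' Spatial phase-weight map with cross-faded blob regions
#'
#' Partitions an `ny` x `nx` scan grid into `P` contiguous single-phase
#' regions (nearest-seed cells) and cross-fades linearly between phases over
#' a band of `mix_width` pixels at region boundaries, emulating the mixed
#' illuminated volumes found at phase interfaces. With `mix_width = 0` the
#' map is a hard segmentation.
#'
#' @param ny,nx grid dimensions (rows, columns).
#' @param P number of phases, >= 2.
#' @param mix_width cross-fade band width in pixels; must be smaller than
#'   `min(ny, nx)`.
#' @param seed integer seed for the seed-pixel draw; ignored when `centers`
#'   is supplied.
#' @param centers optional P x 2 matrix of (row, col) region seed positions
#'   (1-based, may be fractional). Defaults to a pseudo-random
#'   farthest-point spread.
#' @return `ny x nx x P` array of nonnegative weights summing to 1 per pixel.
#' @export
blob_weight_map <- function(ny, nx, P, mix_width = 0, seed = 1L,
                            centers = NULL) {
  stopifnot(ny >= 1, nx >= 1)
  if (P < 2) stop("at least two phases are required (P >= 2)", call. = FALSE)
  if (mix_width >= min(ny, nx)) {
    stop("mix_width must be smaller than the shortest grid side", call. = FALSE)
  }
  if (mix_width < 0) stop("mix_width must be >= 0", call. = FALSE)
  if (is.null(centers)) {
    centers <- spread_centers(ny, nx, P, seed)
  }
  centers <- as.matrix(centers)
  stopifnot(nrow(centers) == P, ncol(centers) == 2)

  rows <- matrix(seq_len(ny), ny, nx)
  cols <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  d <- array(0, dim = c(ny, nx, P))
  for (p in seq_len(P)) {
    d[, , p] <- sqrt((rows - centers[p, 1])^2 + (cols - centers[p, 2])^2)
  }
  dmin <- apply(d, c(1, 2), min)
  w <- array(0, dim = c(ny, nx, P))
  if (mix_width == 0) {
    # hard assignment; ties broken toward the lowest phase index
    lab <- apply(d, c(1, 2), which.min)
    for (p in seq_len(P)) w[, , p] <- as.numeric(lab == p)
  } else {
    for (p in seq_len(P)) {
      w[, , p] <- pmax(0, 1 - (d[, , p] - dmin) / mix_width)
    }
    tot <- apply(w, c(1, 2), sum)
    for (p in seq_len(P)) w[, , p] <- w[, , p] / tot
  }
  w
}

# Farthest-point spread of P seed pixels: first seed pseudo-random, each
# subsequent seed maximizes its distance to the ones already placed.
spread_centers <- function(ny, nx, P, seed) {
  rows <- rep(seq_len(ny), nx)
  cols <- rep(seq_len(nx), each = ny)
  centers <- matrix(0, P, 2)
  idx <- local_seed(seed, sample.int(ny * nx, 1L))
  centers[1, ] <- c(rows[idx], cols[idx])
  if (P > 1) {
    dmin <- sqrt((rows - centers[1, 1])^2 + (cols - centers[1, 2])^2)
    for (p in 2:P) {
      idx <- which.max(dmin)
      centers[p, ] <- c(rows[idx], cols[idx])
      dnew <- sqrt((rows - centers[p, 1])^2 + (cols - centers[p, 2])^2)
      dmin <- pmin(dmin, dnew)
    }
  }
  centers
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Quadrant weight map
#'
#' Convenience wrapper around [blob_weight_map()] with seeds at the quadrant
#' centers of the grid, producing the canonical four-phase quadrant phantom
#' (optionally cross-faded).
#'
#' @inheritParams blob_weight_map
#' @export
quadrant_weight_map <- function(ny, nx, mix_width = 0) {
  centers <- rbind(
    c((ny + 1) / 4, (nx + 1) / 4),
    c((ny + 1) / 4, 3 * (nx + 1) / 4),
    c(3 * (ny + 1) / 4, (nx + 1) / 4),
    c(3 * (ny + 1) / 4, 3 * (nx + 1) / 4))
  blob_weight_map(ny, nx, P = 4, mix_width = mix_width, centers = centers)
}

#' Specify a synthetic scanning-scattering phantom
#'
#' @param q_grid strictly increasing positive q values (nm^-1), length
#'   `c_raw`.
#' @param phases list of [phase_spectrum()] objects (length P >= 2).
#' @param weight_map `ny x nx x P` array of nonnegative per-pixel phase
#'   weights summing to 1.
#' @param counts_scale expected total photon counts per curve (Poisson
#'   intensity budget); >= 0.
#' @param seed integer RNG seed; part of the phantom identity so that the
#'   same spec always produces bit-identical data.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(q_grid, phases, weight_map, counts_scale = 1e5,
                         seed = 1L) {
  check_q_grid(q_grid)
  stopifnot(is.list(phases))
  if (length(phases) < 2) stop("P >= 2 phases required", call. = FALSE)
  for (ph in phases) stopifnot(inherits(ph, "phase_spectrum"))
  dm <- dim(weight_map)
  if (length(dm) != 3 || dm[3] != length(phases)) {
    stop("weight_map must be ny x nx x P with P = length(phases)", call. = FALSE)
  }
  ny <- dm[1]; nx <- dm[2]; P <- dm[3]
  if (ny * nx < 4 * P) {
    stop("grid too small: need ny*nx >= 4*P pixels for per-phase statistics",
         call. = FALSE)
  }
  if (any(weight_map < 0)) stop("weights must be nonnegative", call. = FALSE)
  tot <- apply(weight_map, c(1, 2), sum)
  if (any(abs(tot - 1) > 1e-9)) {
    bad <- which(abs(tot - 1) > 1e-9, arr.ind = TRUE)[1, ]
    stop(sprintf("phase weights at pixel (%d,%d) sum to %.6f, not 1",
                 bad[1], bad[2], tot[bad[1], bad[2]]), call. = FALSE)
  }
  qr <- range(q_grid)
  for (ph in phases) {
    if (nrow(ph$peaks) > 0 &&
        (any(ph$peaks$center < qr[1]) || any(ph$peaks$center > qr[2]))) {
      stop("all peak centers must lie inside the phantom q range", call. = FALSE)
    }
  }
  if (counts_scale < 0) stop("counts_scale must be >= 0", call. = FALSE)
  structure(
    list(q_grid = q_grid, phases = phases, weight_map = weight_map,
         counts_scale = counts_scale, seed = as.integer(seed),
         ny = ny, nx = nx, P = P),
    class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %dx%d scan, %d phases, %d q points, counts_scale=%g, seed=%d\n",
              x$ny, x$nx, x$P, length(x$q_grid), x$counts_scale, x$seed))
  invisible(x)
}

#' Generate a synthetic scanning-scattering dataset
#'
#' Evaluates every phase spectrum on the q grid, mixes them linearly per
#' pixel according to the weight map (incoherent phase addition), scales each
#' clean curve so its expected total counts equal `counts_scale`, and draws
#' independent Poisson counts per (pixel, q) channel. Curves are stored in
#' row-major raster order (pixel index k maps to row `(k-1) %/% nx`, column
#' `(k-1) %% nx`, 0-based).
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_truth` with elements `spec`,
#'   `clean_curves` (r x c_raw), `noisy_curves` (r x c_raw),
#'   `true_labels` (ny x nx, argmax phase weight), `mixed` (ny x nx logical,
#'   TRUE where the maximum weight is below 0.5; such interface pixels are
#'   excluded from segmentation-accuracy scoring), and `grid` (a
#'   [scan_grid()]).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  ny <- spec$ny; nx <- spec$nx; P <- spec$P
  r <- ny * nx
  c_raw <- length(spec$q_grid)

  S <- t(vapply(spec$phases, evaluate_phase, numeric(c_raw),
                q_grid = spec$q_grid))          # P x c_raw
  if (any(S <= 0)) {
    stop("phase spectra must evaluate strictly positive on the q grid",
         call. = FALSE)
  }
  # weight matrix in row-major raster order
  W <- matrix(0, r, P)
  for (p in seq_len(P)) {
    W[, p] <- as.vector(t(spec$weight_map[, , p]))
  }
  clean <- W %*% S                              # r x c_raw

  lambda <- clean * (spec$counts_scale / rowSums(clean))
  noisy <- local_seed(spec$seed, {
    matrix(stats::rpois(r * c_raw, as.vector(lambda)), r, c_raw)
  })
  noisy <- matrix(as.numeric(noisy), r, c_raw)

  wmax <- apply(spec$weight_map, c(1, 2), max)
  lab <- apply(spec$weight_map, c(1, 2), which.max)
  structure(
    list(spec = spec, clean_curves = clean, noisy_curves = noisy,
         true_labels = lab, mixed = wmax < 0.5,
         grid = scan_grid(ny, nx)),
    class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d curves x %d q, %d phases, %d mixed interface pixels\n",
              nrow(x$noisy_curves), ncol(x$noisy_curves), x$spec$P,
              sum(x$mixed)))
  invisible(x)
}

#' Default four-phase demonstration phantom
#'
#' A 32 x 32 quadrant scan over q = 0.5..25 nm^-1 (1000 raw channels) with
#' four distinct phases spanning the behaviors the classifier keys on: a
#' lamellar lipid-like phase (sharp peak near q = 1.47 nm^-1 plus its
#' second order), a collagen-like low-q phase, a crystalline mineral-like
#' phase (two wide-angle Bragg lines), and a broad amorphous halo, each on
#' its own power-law-plus-flat background. Peak centers sit at centers of
#' the default log-rebinned channels and peak widths span at least two of
#' them, so every phase's inflection features are resolvable at the
#' working resolution of the standard pipeline (rebinning factor 10).
#' Expected counts default to 1e5 per curve.
#'
#' @param seed integer seed.
#' @param ny,nx scan dimensions.
#' @param counts_scale expected total counts per curve.
#' @param mix_width interface cross-fade width in pixels (0 = hard
#'   boundaries).
#' @return A [phantom_spec()].
#' @export
default_phantom_spec <- function(seed = 42L, ny = 32, nx = 32,
                                 counts_scale = 1e5, mix_width = 0) {
  c_raw <- 1000L
  q <- exp(seq(log(0.5), log(25), length.out = c_raw))
  # centers of the 100 working channels after log rebinning by 10
  edges <- exp(seq(log(0.5), log(25), length.out = 101))
  ctr <- sqrt(edges[-1] * edges[-101])
  du <- log(ctr[2] / ctr[1])
  pk <- function(bin, amp, nbins = 2) {
    data.frame(center = ctr[bin], width = ctr[bin] * (exp(nbins * du) - 1),
               amplitude = amp)
  }
  phases <- list(
    phase_spectrum(rbind(pk(28, 12), pk(46, 5)),
                   powerlaw_exponent = 1.8, powerlaw_amplitude = 0.5,
                   flat_background = 0.5, name = "lamellar"),
    phase_spectrum(rbind(pk(9, 10), pk(18, 6)),
                   powerlaw_exponent = 2.2, powerlaw_amplitude = 0.8,
                   flat_background = 0.3, name = "collagen_like"),
    phase_spectrum(rbind(pk(83, 10), pk(91, 7)),
                   powerlaw_exponent = 1.0, powerlaw_amplitude = 0.3,
                   flat_background = 0.5, name = "mineral_like"),
    phase_spectrum(rbind(pk(60, 6, 3), pk(73, 4, 3)),
                   powerlaw_exponent = 0.6, powerlaw_amplitude = 0.2,
                   flat_background = 1.0, name = "amorphous"))
  phantom_spec(q, phases, quadrant_weight_map(ny, nx, mix_width = mix_width),
               counts_scale = counts_scale, seed = seed)
}

#' True phase spectra of a phantom, on any q grid
#'
#' @param spec a [phantom_spec()].
#' @param q_grid grid to evaluate on; defaults to the phantom's own.
#' @return P x length(q_grid) matrix of clean phase intensities.
#' @export
phantom_phase_curves <- function(spec, q_grid = spec$q_grid) {
  t(vapply(spec$phases, evaluate_phase, numeric(length(q_grid)),
           q_grid = q_grid))
}
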
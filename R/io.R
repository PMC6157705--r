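#' Scan-grid geometry
#'
#' Describes how the linear curve index maps to scan pixels. In `row_major`
#' raster order curve k (1-based) sits at 0-based (row, col) =
#' `((k-1) %/% nx, (k-1) %% nx)`. In `snake` order (continuous scans whose
#' return lines are recorded in reverse) odd rows (0-based) are reversed.
#'
#' @param ny,nx positive integers, scan rows and columns.
#' @param raster `"row_major"` (default) or `"snake"`.
#' @param pixel_size optional length-2 numeric `(dx, dy)` step sizes.
#' @return An object of class `scan_grid`.
#' @export
scan_grid <- function(ny, nx, raster = c("row_major", "snake"),
                      pixel_size = NULL) {
  raster <- match.arg(raster)
  stopifnot(is.numeric(ny), is.numeric(nx), ny >= 1, nx >= 1,
            ny == round(ny), nx == round(nx))
  structure(list(ny = as.integer(ny), nx = as.integer(nx), raster = raster,
                 pixel_size = pixel_size),
            class = "scan_grid")
}

#' @export
print.scan_grid <- function(x, ...) {
  cat(sprintf("<scan_grid> %d x %d, raster=%s\n", x$ny, x$nx, x$raster))
  invisible(x)
}

#' Map linear curve indices to scan pixels
#'
#' @param grid a [scan_grid()].
#' @param k 1-based linear curve indices.
#' @return Integer matrix with columns `row`, `col` (0-based).
#' @export
index_to_pixel <- function(grid, k = seq_len(grid$ny * grid$nx)) {
  stopifnot(inherits(grid, "scan_grid"))
  k0 <- as.integer(k) - 1L
  row <- k0 %/% grid$nx
  col <- k0 %% grid$nx
  if (grid$raster == "snake") {
    odd <- row %% 2L == 1L
    col[odd] <- grid$nx - 1L - col[odd]
  }
  cbind(row = row, col = col)
}

#' Map scan pixels to linear curve indices
#'
#' Inverse of [index_to_pixel()].
#'
#' @param grid a [scan_grid()].
#' @param row,col 0-based pixel coordinates.
#' @return 1-based linear indices.
#' @export
pixel_to_index <- function(grid, row, col) {
  stopifnot(inherits(grid, "scan_grid"))
  col <- as.integer(col); row <- as.integer(row)
  if (grid$raster == "snake") {
    odd <- row %% 2L == 1L
    col[odd] <- grid$nx - 1L - col[odd]
  }
  row * grid$nx + col + 1L
}

#' Single scattering curve
#'
#' @param q strictly increasing positive q grid (nm^-1), length >= 8.
#' @param intensity nonnegative finite intensities, same length as `q`.
#' @param pixel optional `(row, col)` scan indices (0-based).
#' @param transmission optional scalar in (0, 1].
#' @return An object of class `scattering_curve`.
#' @export
scattering_curve <- function(q, intensity, pixel = NULL, transmission = NULL) {
  if (length(q) < 8) stop("a curve needs at least 8 q points", call. = FALSE)
  check_q_grid(q)
  if (length(intensity) != length(q)) {
    stop("q and intensity lengths differ", call. = FALSE)
  }
  if (any(!is.finite(intensity))) stop("intensities must be finite", call. = FALSE)
  if (any(intensity < 0)) stop("intensities must be nonnegative", call. = FALSE)
  if (!is.null(transmission)) {
    stopifnot(length(transmission) == 1, transmission > 0, transmission <= 1)
  }
  structure(list(q = as.numeric(q), intensity = as.numeric(intensity),
                 pixel = pixel, transmission = transmission),
            class = "scattering_curve")
}

fmt_num <- function(x) sprintf("%.17g", x)

meta_header <- function(grid) {
  c(sprintf("# ny=%d", grid$ny), sprintf("# nx=%d", grid$nx),
    sprintf("# raster=%s", grid$raster))
}

parse_meta <- function(lines) {
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)=(\\S+)", ln))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- m[3]
  }
  kv
}

#' Write a stack of scattering curves
#'
#' Two container formats are supported: delimited text (`"tsv"`; comment
#' header with the grid geometry, a `q` column, then one intensity column
#' per scan pixel in raster order, full double precision) and a binary
#' named-array container (`"rds"`; a list with `q`, `intensities`, `grid`).
#'
#' @param q shared q grid.
#' @param intensities r x c matrix, one row per curve, raster order.
#' @param grid a [scan_grid()] with `ny*nx == nrow(intensities)`.
#' @param path output file.
#' @param format `"tsv"` or `"rds"`; default guessed from the extension.
#' @export
write_curve_stack <- function(q, intensities, grid, path,
                              format = guess_format(path)) {
  check_q_grid(q)
  intensities <- as.matrix(intensities)
  if (ncol(intensities) != length(q)) {
    stop("intensity columns must match the q grid length", call. = FALSE)
  }
  if (nrow(intensities) != grid$ny * grid$nx) {
    stop(sprintf("curve count %d does not match grid %dx%d",
                 nrow(intensities), grid$ny, grid$nx), call. = FALSE)
  }
  format <- match.arg(format, c("tsv", "rds"))
  if (format == "rds") {
    saveRDS(list(q = q, intensities = intensities, grid = grid), path)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header(grid), con)
  header <- c("q", sprintf("curve_%05d", seq_len(nrow(intensities))))
  writeLines(paste(header, collapse = "\t"), con)
  body <- cbind(fmt_num(q), apply(intensities, 1, fmt_num))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

guess_format <- function(path) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "tsv"
}

#' Read a stack of scattering curves
#'
#' Counterpart of [write_curve_stack()]; validates grid consistency (the
#' number of curves must equal `ny * nx`) and the shared q grid (strictly
#' increasing, positive).
#'
#' @param path input file.
#' @param format `"tsv"` or `"rds"`; default guessed from the extension.
#' @return List with `q`, `intensities` (r x c matrix, raster order) and
#'   `grid`.
#' @export
read_curve_stack <- function(path, format = guess_format(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- match.arg(format, c("tsv", "rds"))
  if (format == "rds") {
    obj <- readRDS(path)
    if (!all(c("q", "intensities", "grid") %in% names(obj))) {
      stop("binary container must hold named arrays q, intensities, grid",
           call. = FALSE)
    }
    out <- list(q = obj$q, intensities = as.matrix(obj$intensities),
                grid = obj$grid)
  } else {
    lines <- readLines(path)
    meta_lines <- grep("^#", lines, value = TRUE)
    kv <- parse_meta(meta_lines)
    if (is.null(kv$ny) || is.null(kv$nx)) {
      stop("curve stack header must declare ny and nx", call. = FALSE)
    }
    grid <- scan_grid(as.integer(kv$ny), as.integer(kv$nx),
                      raster = if (is.null(kv$raster)) "row_major" else kv$raster)
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             comment.char = "#", check.names = FALSE)
    out <- list(q = as.numeric(tab[[1]]),
                intensities = t(as.matrix(tab[, -1, drop = FALSE])),
                grid = grid)
    dimnames(out$intensities) <- NULL
    storage.mode(out$intensities) <- "double"
  }
  tryCatch(check_q_grid(out$q),
           error = function(e) stop("curve stack q grid: ",
                                    conditionMessage(e), call. = FALSE))
  r <- nrow(out$intensities)
  if (r != out$grid$ny * out$grid$nx) {
    stop(sprintf("curve stack has %d curves but grid is %dx%d", r,
                 out$grid$ny, out$grid$nx), call. = FALSE)
  }
  if (ncol(out$intensities) != length(out$q)) {
    stop("curve length does not match the q grid", call. = FALSE)
  }
  out
}

#' Label map of a segmented scan
#'
#' @param labels ny x nx integer matrix, values in 1..n or 0 for
#'   unassigned/excluded pixels.
#' @param grid a [scan_grid()] of matching dimensions.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, grid) {
  labels <- as.matrix(labels)
  stopifnot(inherits(grid, "scan_grid"))
  if (!all(dim(labels) == c(grid$ny, grid$nx))) {
    stop("label matrix dimensions must match the grid", call. = FALSE)
  }
  if (any(labels != round(labels)) || any(labels < 0)) {
    stop("labels must be nonnegative integers", call. = FALSE)
  }
  lab <- sort(unique(labels[labels > 0]))
  if (length(lab) > 0 && !identical(as.integer(lab), seq_len(max(lab)))) {
    stop("assigned labels must form the set 1..n", call. = FALSE)
  }
  structure(list(labels = matrix(as.integer(labels), grid$ny, grid$nx),
                 grid = grid, n = if (length(lab)) max(lab) else 0L),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %dx%d, %d clusters, %d unassigned\n",
              x$grid$ny, x$grid$nx, x$n, sum(x$labels == 0)))
  invisible(x)
}

# Fixed categorical palette keyed by label (Okabe-Ito, colorblind safe);
# label 0 (unassigned) renders dark grey.
label_palette <- function(n) {
  pal <- grDevices::palette.colors(n = 9, palette = "Okabe-Ito")[-1]
  if (n > length(pal)) pal <- rep_len(pal, n)
  unname(pal[seq_len(n)])
}

#' Write a label map as a color image plus text sidecar
#'
#' The image is a PNG rendered with a fixed categorical palette keyed by
#' label; the sidecar is a CSV of `(row, col, label)` with 0-based pixel
#' coordinates and carries the grid geometry in comment lines, so that
#' [read_label_map()] restores the map exactly.
#'
#' @param map a [label_map()].
#' @param path output PNG path; the sidecar is written next to it with a
#'   `.csv` extension unless `sidecar` is given.
#' @param sidecar optional sidecar CSV path.
#' @export
write_label_map <- function(map, path, sidecar = NULL) {
  stopifnot(inherits(map, "label_map"))
  if (is.null(sidecar)) sidecar <- sub("\\.[A-Za-z]+$", "", path)
  if (!grepl("\\.csv$", sidecar)) sidecar <- paste0(sidecar, ".csv")

  cols <- c("#404040", label_palette(max(map$n, 1L)))
  rgb <- grDevices::col2rgb(cols[map$labels + 1L]) / 255
  img <- array(0, dim = c(map$grid$ny, map$grid$nx, 3))
  for (ch in 1:3) img[, , ch] <- matrix(rgb[ch, ], map$grid$ny, map$grid$nx)
  png::writePNG(img, path)

  px <- index_to_pixel(map$grid)
  lab <- vapply(seq_len(nrow(px)),
                function(k) map$labels[px[k, 1] + 1L, px[k, 2] + 1L],
                integer(1))
  con <- file(sidecar, "w")
  on.exit(close(con))
  writeLines(meta_header(map$grid), con)
  writeLines("row,col,label", con)
  writeLines(sprintf("%d,%d,%d", px[, 1], px[, 2], lab), con)
  invisible(c(image = path, sidecar = sidecar))
}

#' Read a label map from its text sidecar
#'
#' @param sidecar CSV sidecar written by [write_label_map()].
#' @return A [label_map()].
#' @export
read_label_map <- function(sidecar) {
  if (!file.exists(sidecar)) stop("file not found: ", sidecar, call. = FALSE)
  kv <- parse_meta(grep("^#", readLines(sidecar), value = TRUE))
  grid <- scan_grid(as.integer(kv$ny), as.integer(kv$nx),
                    raster = if (is.null(kv$raster)) "row_major" else kv$raster)
  tab <- utils::read.csv(sidecar, comment.char = "#")
  labels <- matrix(0L, grid$ny, grid$nx)
  labels[cbind(tab$row + 1L, tab$col + 1L)] <- as.integer(tab$label)
  label_map(labels, grid)
}

#' Write representative signals as a delimited table
#'
#' One `q` column plus one column per representative, named `S_1..S_n`; the
#' extraction method is recorded in a comment header line.
#'
#' @param reps list of representative signals (see
#'   [extract_representatives()]); all must share one q grid.
#' @param q the working q grid the curves live on.
#' @param path output TSV path.
#' @export
write_representatives <- function(reps, q, path) {
  if (length(reps) == 0) {
    stop("no representative signals to write", call. = FALSE)
  }
  lens <- vapply(reps, function(r) length(r$curve), integer(1))
  if (any(lens != length(q))) {
    stop("all representatives must share the working q grid", call. = FALSE)
  }
  methods <- unique(vapply(reps, function(r) r$method, character(1)))
  ids <- vapply(reps, function(r) r$cluster_id, integer(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# method=%s", paste(methods, collapse = ",")), con)
  writeLines(paste(c("q", sprintf("S_%d", ids)), collapse = "\t"), con)
  mat <- cbind(q, do.call(cbind, lapply(reps, function(r) r$curve)))
  writeLines(apply(matrix(fmt_num(mat), nrow(mat), ncol(mat)), 1,
                   paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a representative-signal table
#'
#' @param path TSV written by [write_representatives()].
#' @return List with `q`, `signals` (matrix, one column per S_i), `method`.
#' @export
read_representatives <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  kv <- parse_meta(grep("^#", readLines(path), value = TRUE))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           check.names = FALSE)
  list(q = tab[[1]], signals = as.matrix(tab[, -1, drop = FALSE]),
       method = kv$method)
}

#' Write a phantom dataset to disk
#'
#' Emits the noisy curve stack in the standard container format, the
#' ground-truth label image (PNG + CSV sidecar), and a truth table
#' (`truth_weights.csv`: pixel coordinates plus the per-phase weights).
#'
#' @param truth a `phantom_truth` from [generate_phantom()].
#' @param dir output directory, created if needed.
#' @param format curve container format, `"tsv"` or `"rds"`.
#' @return Named character vector of the files written.
#' @export
write_phantom <- function(truth, dir, format = c("tsv", "rds")) {
  stopifnot(inherits(truth, "phantom_truth"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  curves <- file.path(dir, paste0("curves.", format))
  write_curve_stack(truth$spec$q_grid, truth$noisy_curves, truth$grid, curves,
                    format = format)
  lm <- label_map(truth$true_labels, truth$grid)
  files <- write_label_map(lm, file.path(dir, "truth_labels.png"),
                           file.path(dir, "truth_labels.csv"))
  px <- index_to_pixel(truth$grid)
  W <- matrix(0, nrow(px), truth$spec$P)
  for (p in seq_len(truth$spec$P)) {
    W[, p] <- truth$spec$weight_map[cbind(px[, 1] + 1L, px[, 2] + 1L, p)]
  }
  wt <- data.frame(row = px[, 1], col = px[, 2], W)
  names(wt)[-(1:2)] <- sprintf("w_%d", seq_len(truth$spec$P))
  weights <- file.path(dir, "truth_weights.csv")
  utils::write.csv(wt, weights, row.names = FALSE, quote = FALSE)
  invisible(c(curves = curves, files, weights = weights))
}
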
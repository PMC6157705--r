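#' Convert a real-space spacing to a scattering-vector position
#'
#' Bragg's relation for the scattering vector magnitude: a lattice or
#' lamellar repeat distance d produces a peak at q = 2*pi/d. For example
#' the ~4.26 nm lamellar repeat of stacked lipid bilayers gives a peak near
#' q = 1.47 nm^-1.
#'
#' @param d real-space spacing (nm).
#' @return q position (nm^-1).
#' @export
d_spacing_to_q <- function(d) {
  stopifnot(all(d > 0))
  2 * pi / d
}

#' Convert a scattering-vector position to a real-space spacing
#'
#' @param q scattering-vector magnitude (nm^-1).
#' @return d spacing (nm).
#' @export
q_to_d_spacing <- function(q) {
  stopifnot(all(q > 0))
  2 * pi / q
}

#' Segmentation accuracy against ground-truth labels
#'
#' Fraction of scored pixels whose predicted label matches the truth under
#' the best one-to-one relabeling (cluster labels are arbitrary, so all
#' injective assignments of predicted to true labels are searched).
#' Pixels flagged mixed (interface pixels whose maximum phase weight is
#' below 0.5) and unassigned pixels (label 0) are excluded from scoring.
#'
#' @param predicted a [label_map()] or ny x nx integer matrix.
#' @param truth ny x nx integer matrix of true labels.
#' @param mixed optional ny x nx logical matrix of pixels to exclude.
#' @return List: `accuracy` (fraction in [0, 1]), `mapping` (named vector,
#'   predicted -> true), `n_scored`.
#' @export
segmentation_accuracy <- function(predicted, truth, mixed = NULL) {
  pred <- if (inherits(predicted, "label_map")) predicted$labels else as.matrix(predicted)
  truth <- as.matrix(truth)
  stopifnot(all(dim(pred) == dim(truth)))
  score <- pred > 0
  if (!is.null(mixed)) score <- score & !mixed
  p <- pred[score]
  t <- truth[score]
  pl <- sort(unique(p)); tl <- sort(unique(t))
  C <- table(factor(p, levels = pl), factor(t, levels = tl))
  # assignment by exhaustive search over injections of the smaller side
  np <- length(pl); nt <- length(tl)
  swap <- np > nt
  if (swap) C <- t(C)
  perms <- permutations_of(ncol(C), nrow(C))
  best <- 0; best_perm <- perms[[1]]
  for (pm in perms) {
    s <- sum(C[cbind(seq_len(nrow(C)), pm)])
    if (s > best) { best <- s; best_perm <- pm }
  }
  mapping <- if (swap) {
    stats::setNames(rep(NA_integer_, np), pl)
  } else {
    stats::setNames(tl[best_perm], pl)
  }
  if (swap) mapping[as.character(pl[best_perm])] <- tl
  list(accuracy = best / length(p), mapping = mapping, n_scored = length(p))
}

# All injections of 1..k into 1..n as index vectors (k <= n, n <= 8).
permutations_of <- function(n, k = n) {
  stopifnot(k <= n, n <= 10)
  if (k == 0) return(list(integer(0)))
  out <- list()
  rec <- function(prefix, remaining) {
    if (length(prefix) == k) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (x in remaining) rec(c(prefix, x), setdiff(remaining, x))
  }
  rec(integer(0), seq_len(n))
  out
}
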
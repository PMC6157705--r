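# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles are deliberately naive (explicit loops) so they share
# no code path with the vectorized implementations they check.

# O(r^2) silhouette: textbook definition, one point at a time.
brute_silhouette <- function(scores, labels) {
  scores <- as.matrix(scores)
  r <- nrow(scores)
  s <- numeric(r)
  for (i in seq_len(r)) {
    own <- labels == labels[i]
    n_own <- sum(own)
    if (n_own == 1) {
      s[i] <- 0
      next
    }
    d <- function(j) sqrt(sum((scores[i, ] - scores[j, ])^2))
    a <- mean(vapply(setdiff(which(own), i), d, numeric(1)))
    b <- Inf
    for (g in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(vapply(which(labels == g), d, numeric(1))))
    }
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# Pearson correlation straight from the covariance formula, (n-1)
# convention, no clamping.
brute_pearson <- function(x, y) {
  n <- length(x)
  cv <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sx <- sqrt(sum((x - mean(x))^2) / (n - 1))
  sy <- sqrt(sum((y - mean(y))^2) / (n - 1))
  cv / (sx * sy)
}

# Log-binning oracle: loop over output bins, average members directly.
brute_log_resample <- function(q, intensity, factor) {
  c_out <- ceiling(length(q) / factor)
  edges <- exp(seq(log(min(q)), log(max(q)), length.out = c_out + 1))
  vals <- rep(NA_real_, c_out)
  for (j in seq_len(c_out)) {
    lo <- edges[j]; hi <- edges[j + 1]
    inside <- if (j == c_out) q >= lo & q <= hi else q >= lo & q < hi
    if (any(inside)) vals[j] <- mean(intensity[inside])
  }
  list(centers = sqrt(edges[-1] * edges[-(c_out + 1)]), values = vals)
}

# Small two-phase phantom for cheap end-to-end tests.
small_phantom_spec <- function(seed = 1L, ny = 8, nx = 8, counts_scale = 1e5,
                               mix_width = 0) {
  q <- exp(seq(log(0.5), log(25), length.out = 200))
  phases <- list(
    phase_spectrum(data.frame(center = 1.5, width = 0.25, amplitude = 10),
                   powerlaw_exponent = 1.5, powerlaw_amplitude = 0.3,
                   flat_background = 0.5, name = "A"),
    phase_spectrum(data.frame(center = 10, width = 1.6, amplitude = 10),
                   powerlaw_exponent = 0.8, powerlaw_amplitude = 0.2,
                   flat_background = 0.5, name = "B"))
  w <- blob_weight_map(ny, nx, P = 2, mix_width = mix_width,
                       centers = rbind(c((ny + 1) / 2, 1),
                                       c((ny + 1) / 2, nx)))
  phantom_spec(q, phases, w, counts_scale = counts_scale, seed = seed)
}

# Run the analysis core (preprocess -> features -> PCA -> clustering) on a
# generated phantom; returns every intermediate.
phantom_pipeline_core <- function(spec, seed = spec$seed, restarts = 20) {
  truth <- generate_phantom(spec)
  m1 <- preprocess_curves(spec$q_grid, truth$noisy_curves, grid = truth$grid)
  m2 <- suppressWarnings(detect_features(m1))
  pca <- fit_pca(m2)
  m_sel <- suppressMessages(select_m(pca$explained_ratio))
  scores <- pca$scores[, seq_len(m_sel$m), drop = FALSE]
  model <- select_n_and_fit(scores, seed = seed, restarts = restarts)
  map <- labels_to_map(model$labels, m1$grid, excluded = which(m1$excluded))
  list(truth = truth, m1 = m1, m2 = m2, pca = pca, m_sel = m_sel,
       scores = scores, model = model, map = map)
}
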
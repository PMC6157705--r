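# dense log-spaced grid used by the analytic derivative checks
qd <- exp(seq(log(1), log(9), length.out = 400))

test_that("local polynomial derivatives reproduce constants and lines in log q", {
  vals <- rbind(rep(3, 400),            # constant
                5 * log(qd) + 1)        # exact line in u = log q
  dv <- smooth_and_differentiate(vals, window = 5, polyorder = 2, q = qd)
  expect_equal(max(abs(dv$d1[1, ])), 0, tolerance = 1e-10)
  expect_equal(max(abs(dv$d2[1, ])), 0, tolerance = 1e-10)
  expect_equal(dv$d1[2, ], rep(5, 400), tolerance = 1e-8)
  expect_equal(max(abs(dv$d2[2, ])), 0, tolerance = 1e-8)
})

test_that("a dense noiseless Gaussian peak has d1 zero at mu and d2 zeros near mu +/- sigma", {
  mu <- 3; sigma <- 0.3
  vals <- matrix(exp(-(qd - mu)^2 / (2 * sigma^2)), 1)
  dv <- smooth_and_differentiate(vals, q = qd)
  # scan where the signal lives (far tails underflow to numeric dust)
  region <- which(vals[1, ] > 1e-3)
  d1r <- dv$d1[1, region]; d2r <- dv$d2[1, region]
  d1x <- region[which(diff(sign(d1r)) != 0)]
  bin_of <- function(x) which.min(abs(qd - x))
  expect_length(d1x, 1)
  expect_lte(abs(d1x - bin_of(mu)), 1)
  d2x <- region[which(diff(sign(d2r)) != 0)]
  expect_length(d2x, 2)
  # d/d(log q) shifts the curvature zeros by O(sigma^2/mu); allow 2 bins
  expect_lte(abs(d2x[1] - bin_of(mu - sigma)), 2)
  expect_lte(abs(d2x[2] - bin_of(mu + sigma)), 2)
})

test_that("derivative window preconditions are enforced", {
  vals <- matrix(1, 1, 10)
  q10 <- exp(seq(log(1), log(2), length.out = 10))
  expect_error(smooth_and_differentiate(vals, window = 4, q = q10), "odd")
  expect_error(smooth_and_differentiate(vals, window = 11, q = q10), "larger")
  expect_error(smooth_and_differentiate(vals, window = 5, polyorder = 5,
                                        q = q10), "polyorder")
})

test_that("inflection detection finds peak features and ignores monotone power laws", {
  # monotone power law: no zero of dI/du or d2I/du2 -> empty set
  pl <- matrix(qd^-2.5, 1)
  dv <- smooth_and_differentiate(pl, q = qd)
  expect_length(find_inflections(dv$d1[1, ], dv$d2[1, ]), 0)

  # single Gaussian peak -> exactly 3 features (mu - sigma, mu, mu + sigma)
  mu <- 3; sigma <- 0.3
  g1 <- matrix(exp(-(qd - mu)^2 / (2 * sigma^2)), 1)
  dvg <- smooth_and_differentiate(g1, q = qd)
  f1 <- find_inflections(dvg$d1[1, ], dvg$d2[1, ])
  expect_equal(length(f1), 3)
  bin_of <- function(x) which.min(abs(qd - x))
  expect_lte(max(abs(f1 - c(bin_of(mu - sigma), bin_of(mu),
                            bin_of(mu + sigma)))), 2)

  # two disjoint Gaussian peaks -> 6 prominent features, matching a
  # brute-force sign-change scan of the analytic derivatives in u = log q
  # (the valley between the peaks also crosses zero analytically, but at
  # underflow-level magnitude; the same relative-prominence rule is
  # applied to the oracle)
  mus <- c(2, 6); sigmas <- c(0.2, 0.5)
  g2 <- matrix(exp(-(qd - mus[1])^2 / (2 * sigmas[1]^2)) +
               exp(-(qd - mus[2])^2 / (2 * sigmas[2]^2)), 1)
  dv2 <- smooth_and_differentiate(g2, q = qd)
  f2 <- find_inflections(dv2$d1[1, ], dv2$d2[1, ])
  expect_equal(length(f2), 6)
  # analytic oracle: dI/du = q dI/dq, d2I/du2 = q d/dq (q dI/dq)
  I <- function(q) exp(-(q - mus[1])^2 / (2 * sigmas[1]^2)) +
                   exp(-(q - mus[2])^2 / (2 * sigmas[2]^2))
  eps <- 1e-6
  d1a <- function(q) q * (I(q + eps) - I(q - eps)) / (2 * eps)
  d2a <- function(q) q * (d1a(q + eps) - d1a(q - eps)) / (2 * eps)
  prominent <- function(d) {
    x <- which(diff(sign(d)) != 0)
    keep <- vapply(x, function(i) {
      max(abs(d[max(1, i - 5):min(length(d), i + 6)])) >= 0.05 * max(abs(d))
    }, logical(1))
    x[keep]
  }
  oracle_bins <- sort(c(prominent(d1a(qd)), prominent(d2a(qd))))
  expect_length(oracle_bins, 6)
  expect_true(all(abs(f2 - oracle_bins) <= 2))
})

test_that("feature detection is shift equivariant on the working grid", {
  # translating a peak by one working bin shifts its features by one bin
  spec <- small_phantom_spec(seed = 1)
  cm <- preprocess_curves(spec$q_grid,
                          matrix(evaluate_phase(spec$phases[[1]],
                                                spec$q_grid), 1))
  dv <- smooth_and_differentiate(cm)
  base <- find_inflections(dv$d1[1, ], dv$d2[1, ])
  shifted <- curve_matrix(cbind(cm$values[, -1, drop = FALSE],
                                cm$values[, ncol(cm$values)]), cm$q)
  dvs <- smooth_and_differentiate(shifted)
  moved <- find_inflections(dvs$d1[1, ], dvs$d2[1, ])
  inner <- base[base > 5 & base < ncol(cm$values) - 5]
  expect_true(all((inner - 1) %in% moved))
})

test_that("the feature matrix unions per-row detections and zero-fills", {
  q20 <- exp(seq(log(1), log(10), length.out = 20))
  vals <- matrix(1, 5, 20)
  cm <- curve_matrix(vals, q20)
  infl <- list(c(3, 7, 12), c(3, 7, 12), c(5, 15), c(5, 15), integer(0))
  fm <- build_feature_matrix(cm, infl)
  # union of disjoint sets of sizes 3 and 2 -> d = 5
  expect_equal(fm$feature_bins, c(3, 5, 7, 12, 15))
  expect_equal(fm$feature_q, q20[c(3, 5, 7, 12, 15)])
  # each detected entry equals the source intensity; others zero
  expect_equal(fm$values[1, ], c(1, 0, 1, 1, 0))
  expect_equal(fm$values[3, ], c(0, 1, 0, 0, 1))
  expect_true(all(rowSums(fm$values[1:2, ] == 0) == 2))
  # featureless row retained as all-zero
  expect_equal(fm$values[5, ], rep(0, 5))

  # all rows identical with 3 inflections -> d = 3, no zeros
  fm2 <- build_feature_matrix(cm, rep(list(c(3, 7, 12)), 5))
  expect_equal(ncol(fm2$values), 3)
  expect_true(all(fm2$values != 0))

  expect_error(build_feature_matrix(cm, rep(list(integer(0)), 5)),
               "no features")
})

test_that("feature values are drawn verbatim from the curve matrix", {
  spec <- small_phantom_spec(seed = 3)
  truth <- generate_phantom(spec)
  m1 <- preprocess_curves(spec$q_grid, truth$noisy_curves, grid = truth$grid)
  m2 <- suppressWarnings(detect_features(m1))
  src <- m1$values[, m2$feature_bins, drop = FALSE]
  expect_true(all(m2$values == src | m2$values == 0))
  expect_lt(ncol(m2$values), ncol(m1$values))  # d < c
})
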
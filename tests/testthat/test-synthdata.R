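test_that("phase spectra evaluate to the analytic Gaussian + power-law + flat form", {
  q <- seq(0.5, 5, length.out = 10)

  peak <- phase_spectrum(data.frame(center = 2, width = 0.1, amplitude = 1))
  expect_equal(evaluate_phase(peak, c(1, 2, 3))[2], 1.0)

  powerlaw <- phase_spectrum(powerlaw_exponent = 2, powerlaw_amplitude = 1)
  expect_equal(evaluate_phase(powerlaw, c(1, 2))[2], 0.25)

  flat <- phase_spectrum(flat_background = 3.5)
  expect_equal(evaluate_phase(flat, q), rep(3.5, 10))

  # superposition of the three terms
  combo <- phase_spectrum(data.frame(center = 2, width = 0.1, amplitude = 1),
                          powerlaw_exponent = 2, powerlaw_amplitude = 1,
                          flat_background = 3.5)
  expect_equal(evaluate_phase(combo, c(2))[1] - 1 - 0.25 - 3.5, 0,
               tolerance = 1e-12)
})

test_that("invalid phase parameters and geometry are rejected", {
  expect_error(phase_spectrum(data.frame(center = 2, width = 0, amplitude = 1)),
               "width")
  expect_error(phase_spectrum(data.frame(center = 2, width = 1, amplitude = -1)),
               "amplitude")
  expect_error(phase_spectrum(powerlaw_exponent = -1), "powerlaw_exponent")
  ph <- phase_spectrum(flat_background = 1)
  expect_error(evaluate_phase(ph, c(-1, 1, 2)), "positive")
  expect_error(evaluate_phase(ph, c(2, 1, 3)), "increasing")
})

test_that("weight maps are normalized, hard at mix_width 0, and symmetric at gradients", {
  # hard segmentation: every pixel has exactly one unit weight
  w <- blob_weight_map(8, 8, P = 3, mix_width = 0, seed = 5)
  expect_true(all(apply(w, c(1, 2), function(x) sum(x == 1) == 1 &&
                                                sum(x == 0) == 2)))

  # per-pixel normalization for a faded map
  w2 <- blob_weight_map(16, 16, P = 4, mix_width = 5, seed = 3)
  expect_true(all(w2 >= 0))
  expect_equal(apply(w2, c(1, 2), sum), matrix(1, 16, 16))

  # 1-D gradient between two opposing seeds: the midpoint is an even split
  w3 <- blob_weight_map(21, 21, P = 2, mix_width = 10,
                        centers = rbind(c(11, 1), c(11, 21)))
  expect_equal(w3[11, 11, ], c(0.5, 0.5))

  expect_error(blob_weight_map(8, 8, P = 2, mix_width = 8), "mix_width")
  expect_error(blob_weight_map(8, 8, P = 1), "P >= 2")
})

test_that("phantom generation mixes phases linearly and respects pure-phase weights", {
  q <- exp(seq(log(0.5), log(10), length.out = 50))
  p1 <- phase_spectrum(data.frame(center = 2, width = 0.3, amplitude = 5),
                       flat_background = 1)
  p2 <- phase_spectrum(powerlaw_exponent = 1, powerlaw_amplitude = 2,
                       flat_background = 0.5)
  w <- array(0, dim = c(3, 3, 2))
  w[, , 1] <- 1  # every pixel pure phase 1
  spec <- phantom_spec(q, list(p1, p2), w, counts_scale = 1e4, seed = 9)
  truth <- generate_phantom(spec)
  target <- evaluate_phase(p1, q)
  for (i in seq_len(9)) {
    expect_equal(unname(truth$clean_curves[i, ]), target)
  }
  expect_true(all(truth$true_labels == 1))

  # a 50/50 pixel is the exact average of the two phase curves
  w[2, 2, ] <- c(0.5, 0.5)
  spec2 <- phantom_spec(q, list(p1, p2), w, counts_scale = 1e4, seed = 9)
  truth2 <- generate_phantom(spec2)
  k <- pixel_to_index(truth2$grid, 1, 1)  # pixel (1,1) 0-based = row 2, col 2
  expect_equal(truth2$clean_curves[k, ],
               0.5 * evaluate_phase(p1, q) + 0.5 * evaluate_phase(p2, q))
  # with P = 2 the maximum weight is always >= 0.5, so even a 50/50
  # interface pixel is scored (the mixed flag requires max weight < 0.5)
  expect_false(truth2$mixed[2, 2])
  w3 <- array(1 / 3, dim = c(4, 4, 3))
  spec3 <- phantom_spec(q, list(p1, p2, p2), w3, counts_scale = 10, seed = 1)
  expect_true(all(generate_phantom(spec3)$mixed))
})

test_that("counts_scale 0 yields identically zero noisy curves", {
  spec <- small_phantom_spec(seed = 2, counts_scale = 0)
  truth <- generate_phantom(spec)
  expect_true(all(truth$noisy_curves == 0))
})

test_that("phantom generation is bit-identical for an identical spec", {
  spec <- small_phantom_spec(seed = 31)
  t1 <- generate_phantom(spec)
  t2 <- generate_phantom(spec)
  expect_identical(t1$noisy_curves, t2$noisy_curves)
  expect_identical(t1$clean_curves, t2$clean_curves)
  # a different seed gives different noise
  spec2 <- small_phantom_spec(seed = 32)
  expect_false(identical(generate_phantom(spec2)$noisy_curves,
                         t1$noisy_curves))
})

test_that("Poisson noise averages to the clean curve at high counts", {
  # 100 replicate pixels of one pure phase at counts_scale 1e6: the
  # empirical mean deviates from the expected-count curve by < 1%
  # relative RMS (sampling-error bound)
  q <- exp(seq(log(0.5), log(25), length.out = 500))
  p1 <- phase_spectrum(data.frame(center = 3, width = 0.5, amplitude = 10),
                       powerlaw_exponent = 1, powerlaw_amplitude = 1,
                       flat_background = 1)
  p2 <- phase_spectrum(flat_background = 1)
  w <- array(0, dim = c(10, 10, 2))
  w[, , 1] <- 1
  spec <- phantom_spec(q, list(p1, p2), w, counts_scale = 1e6, seed = 77)
  truth <- generate_phantom(spec)
  lambda <- truth$clean_curves[1, ] * 1e6 / sum(truth$clean_curves[1, ])
  emp <- colMeans(truth$noisy_curves)
  rel_rms <- sqrt(sum((emp - lambda)^2)) / sqrt(sum(lambda^2))
  expect_lt(rel_rms, 0.01)
})

test_that("phantom spec validation catches bad weights and out-of-range peaks", {
  q <- exp(seq(log(0.5), log(10), length.out = 50))
  p1 <- phase_spectrum(flat_background = 1)
  p2 <- phase_spectrum(flat_background = 2)
  w <- array(0.6, dim = c(3, 3, 2))  # sums to 1.2
  expect_error(phantom_spec(q, list(p1, p2), w), "sum to")
  w[, , 2] <- 0.4
  expect_silent(phantom_spec(q, list(p1, p2), w))
  p3 <- phase_spectrum(data.frame(center = 50, width = 1, amplitude = 1),
                       flat_background = 1)
  expect_error(phantom_spec(q, list(p3, p2), w), "q range")
})
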
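test_that("PCA recovers exact low-rank structure and uncorrelated scores", {
  set.seed(11)
  # data on a 2-D plane embedded in d = 10
  basis <- matrix(rnorm(20), 2, 10)
  x <- matrix(rnorm(200), 100, 2) %*% basis
  pca <- fit_pca(x)
  cum <- cumsum(pca$explained_ratio)
  expect_equal(cum[2], 1.0, tolerance = 1e-10)

  # reconstruction with all components is exact on noise-free input
  centered <- sweep(x, 2, pca$center)
  recon <- pca$scores %*% t(pca$components)
  expect_lt(sqrt(mean((recon - centered)^2)), 1e-8)

  # scores pairwise uncorrelated
  cors <- cor(pca$scores[, 1:2])
  expect_lt(abs(cors[1, 2]), 1e-6)

  # explained ratios nonincreasing, cumulative <= 1
  expect_true(all(diff(pca$explained_ratio) <= 1e-12))
  expect_lte(max(cum), 1 + 1e-9)

  # degenerate input: one repeated row has zero variance
  expect_error(fit_pca(matrix(1, 5, 3)), "rank-0")
})

test_that("isotropic noise spreads explained variance evenly", {
  set.seed(21)
  x <- matrix(rnorm(5e4), 1e4, 5)
  pca <- fit_pca(x)
  expect_lt(max(abs(pca$explained_ratio - 0.2)), 0.015)
})

test_that("component count selection follows the threshold rule with a knee diagnostic", {
  expect_equal(select_m(c(0.6, 0.36, 0.04))$m, 2)          # 0.96 >= 0.95
  expect_equal(select_m(c(1.0))$m, 1)
  expect_equal(suppressMessages(select_m(rep(0.1, 10))$m), 10)
  expect_equal(select_m(c(0.6, 0.36, 0.04), 0.5)$m, 1)
  expect_error(select_m(c(0.6, 0.4), 0), "threshold")
  expect_error(select_m(c(0.6, 0.4), 1.5), "threshold")
  # knee of an L-curve with a sharp bend sits at the bend
  sel <- suppressMessages(select_m(c(0.5, 0.4, 0.02, 0.02, 0.02, 0.02, 0.02)))
  expect_equal(sel$knee, 2)
})

test_that("mean silhouette equals the brute-force oracle on random instances", {
  set.seed(33)
  for (rep in 1:25) {
    r <- sample(10:60, 1)
    m <- sample(1:4, 1)
    k <- sample(2:min(6, r - 1), 1)
    scores <- matrix(rnorm(r * m), r, m)
    labels <- sample(rep(seq_len(k), length.out = r))
    expect_equal(mean_silhouette(scores, labels),
                 brute_silhouette(scores, labels), tolerance = 1e-12)
  }
})

test_that("silhouette limits and degenerate conventions hold", {
  # two tight, far-separated clusters -> mean silhouette near 1
  set.seed(5)
  scores <- rbind(matrix(rnorm(40, 0, 1e-4), 20, 2),
                  matrix(rnorm(40, 100, 1e-4), 20, 2))
  labels <- rep(1:2, each = 20)
  expect_gt(mean_silhouette(scores, labels), 0.999)

  # all points identical: a = b = 0 handled as 0
  same <- matrix(1, 10, 2)
  expect_equal(mean_silhouette(same, rep(1:2, 5)), 0)

  # singleton clusters score 0
  s3 <- rbind(c(0, 0), c(0.1, 0), c(50, 50))
  expect_equal(mean_silhouette(s3, c(1, 1, 2)),
               brute_silhouette(s3, c(1, 1, 2)), tolerance = 1e-12)

  expect_error(mean_silhouette(matrix(rnorm(10), 5, 2), rep(1, 5)),
               "two clusters")
})

test_that("silhouette-selected k-means recovers well-separated point clouds", {
  set.seed(8)
  centers <- rbind(c(0, 0), c(20, 0), c(0, 20), c(20, 20))
  truth <- rep(1:4, each = 30)
  scores <- centers[truth, ] + matrix(rnorm(240, 0, 0.5), 120, 2)
  model <- select_n_and_fit(scores, seed = 1)
  expect_equal(model$n, 4)
  # labels match cloud membership up to permutation
  tab <- table(model$labels, truth)
  expect_equal(sum(apply(tab, 1, max)), 120)
  expect_true(all(model$mean_silhouette >= -1 & model$mean_silhouette <= 1,
                  na.rm = TRUE))
  # selected n maximizes the silhouette table
  expect_equal(unname(model$mean_silhouette[as.character(model$n)]),
               max(model$mean_silhouette, na.rm = TRUE))
})

test_that("k-means on {0,1,10,11} picks two clusters with exact centroids", {
  scores <- matrix(c(0, 1, 10, 11), 4, 1)
  model <- select_n_and_fit(scores, n_candidates = 2:3, seed = 2)
  # exhaustive-partition oracle: k = 2 split {0,1}|{10,11} has silhouette
  # (computed by the brute-force oracle) higher than any k = 3 partition
  best2 <- brute_silhouette(scores, c(1, 1, 2, 2))
  expect_equal(model$n, 2)
  expect_equal(sort(model$centroids[, 1]), c(0.5, 10.5))
  expect_equal(unname(model$mean_silhouette["2"]), best2, tolerance = 1e-12)
})

test_that("clustering is deterministic given a seed", {
  set.seed(77)
  scores <- matrix(rnorm(200), 100, 2)
  m1 <- select_n_and_fit(scores, seed = 42)
  m2 <- select_n_and_fit(scores, seed = 42)
  expect_identical(m1$labels, m2$labels)
  expect_identical(m1$mean_silhouette, m2$mean_silhouette)
})

test_that("our Lloyd k-means matches stats::kmeans inertia on a reference problem", {
  set.seed(19)
  x <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 6), 50, 2),
             matrix(rnorm(100, c(0, 12)), 50, 2))
  model <- select_n_and_fit(x, n_candidates = 3, seed = 3)
  ref <- kmeans(x, centers = 3, nstart = 20, iter.max = 100)
  expect_equal(model$inertia, ref$tot.withinss, tolerance = 1e-6)
})

test_that("labels are placed on the scan grid per raster convention", {
  g <- scan_grid(2, 2)
  lm <- labels_to_map(c(1, 1, 2, 2), g)
  expect_equal(lm$labels, rbind(c(1L, 1L), c(2L, 2L)))

  gs <- scan_grid(2, 2, raster = "snake")
  lms <- labels_to_map(c(1, 2, 1, 2), gs)
  # snake: second row arrives reversed
  expect_equal(lms$labels, rbind(c(1L, 2L), c(2L, 1L)))

  # one excluded pixel -> exactly one 0
  lme <- labels_to_map(c(1, 1, 2), g, excluded = 2)
  expect_equal(sum(lme$labels == 0), 1)
  expect_equal(lme$labels[1, 2], 0L)

  expect_error(labels_to_map(c(1, 2), g), "does not match")
})

test_that("relabeling clusters permutes colors but not the partition", {
  set.seed(4)
  scores <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 15), 30, 2))
  model <- select_n_and_fit(scores, n_candidates = 2, seed = 1)
  perm <- c(2L, 1L)
  relabeled <- perm[model$labels]
  # identical partitions up to bijection
  expect_equal(length(unique(paste(model$labels, relabeled))), 2)
  # silhouette invariant under relabeling
  expect_equal(mean_silhouette(scores, relabeled),
               mean_silhouette(scores, model$labels), tolerance = 1e-12)
})
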
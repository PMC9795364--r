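test_that("kernel families evaluate their printed forms", {
  for (fam in c("gaussian", "triangular", "uniform")) {
    expect_equal(kernel_function(0, fam, 5), 1)
  }
  expect_equal(kernel_function(5, "gaussian", 5), exp(-1))
  expect_equal(kernel_function(5, "uniform", 5), 0)    # strict D < bandwidth
  expect_equal(kernel_function(4.99, "uniform", 5), 1)
  expect_equal(kernel_function(2, "triangular", 8), 1 - 2 / 8)
  expect_equal(kernel_function(9, "triangular", 8), 0)
  expect_error(kernel_function(1, "gaussian", 0), "positive")
  expect_error(kernel_config(bandwidth = -1), "positive")
})

test_that("kernel weights are region-masked with correct effective neighbors", {
  ## isolated spot in its own region: only itself contributes
  ds <- spatial_dataset(matrix(0, 3, 1), rbind(c(0, 0), c(1, 0), c(50, 50)),
                        c("a", "a", "b"))
  w <- compute_kernel_weights(ds, pairwise_distances(ds))
  expect_equal(w$effective_neighbors[[3]], 1)

  ## coincident same-region spots each see two full-weight neighbors
  ds2 <- spatial_dataset(matrix(0, 2, 1), rbind(c(1, 1), c(1, 1)), c("a", "a"))
  w2 <- compute_kernel_weights(ds2, pairwise_distances(ds2))
  expect_equal(unname(w2$effective_neighbors), c(2, 2))

  ## brute-force oracle on a 7x7 lattice split into two regions
  coords <- as.matrix(expand.grid(x = 1:7, y = 1:7))
  regions <- ifelse(coords[, "x"] <= 3, "left", "right")
  ds7 <- spatial_dataset(matrix(rnorm(49), 49, 1), coords, regions)
  D <- pairwise_distances(ds7)
  w7 <- compute_kernel_weights(ds7, D, kernel_config(bandwidth = 5))
  expect_equal(unname(w7$weights), brute_weights(ds7, D, "gaussian", 5))
  expect_equal(unname(w7$effective_neighbors),
               rowSums(brute_weights(ds7, D, "gaussian", 5)))
})

test_that("effective-neighbors filtering keeps exactly the qualifying spots", {
  coords <- as.matrix(expand.grid(x = 1:7, y = 1:7))
  ds <- spatial_dataset(matrix(rnorm(49), 49, 1), coords, rep("a", 49))
  D <- pairwise_distances(ds)
  w <- compute_kernel_weights(ds, D)

  f0 <- filter_spots(ds, w, 0)
  expect_true(all(f0$kept))

  fk <- filter_spots(ds, w, 10)
  expect_identical(unname(fk$kept), unname(rowSums(brute_weights(ds, D)) >= 10))

  ## a two-spot region cannot reach the default threshold of 10
  tiny <- spatial_dataset(matrix(0, 2, 1), rbind(c(0, 0), c(1, 0)), c("a", "a"))
  wt <- compute_kernel_weights(tiny, pairwise_distances(tiny))
  expect_error(filter_spots(tiny, wt, 10), "threshold 10")
})

test_that("spot-level moment estimates match brute-force kernel estimation", {
  ds <- make_test_dataset(n = 20, m = 3, n_regions = 2, seed = 11)
  D <- pairwise_distances(ds)
  w <- compute_kernel_weights(ds, D)
  genes <- ds$gene_ids
  M <- estimate_spot_means(ds, w, genes)
  V <- estimate_spot_variances(ds, w, M, genes)
  A <- estimate_spot_covariances(ds, w, M, genes)

  W <- brute_weights(ds, D)
  Mb <- brute_means(ds, W, genes)
  expect_equal(unname(M), Mb, tolerance = 1e-12)
  expect_equal(unname(V), brute_variances(ds, W, Mb, genes), tolerance = 1e-12)
  expect_equal(unname(unclass(A)), brute_covariances(ds, W, Mb, genes),
               tolerance = 1e-12)

  ## diagonal of the covariance equals the variance estimate
  for (g in seq_along(genes)) expect_equal(A[, g, g], V[, g])

  ## every per-spot covariance is PSD
  for (i in seq_len(20)) {
    expect_gte(min(eigen(A[i, , ], symmetric = TRUE)$values), -1e-10)
  }
})

test_that("moment estimates honor convexity and degenerate edge cases", {
  expr <- cbind(gA = rep(3, 6), gB = rnorm(6))
  ds <- spatial_dataset(expr, cbind(1:6, 1), rep("a", 6))
  w <- compute_kernel_weights(ds, pairwise_distances(ds))
  M <- estimate_spot_means(ds, w)
  expect_equal(unname(M[, "gA"]), rep(3, 6))
  V <- estimate_spot_variances(ds, w, M)
  expect_equal(unname(V[, "gA"]), rep(0, 6))
  expect_true(all(M[, "gB"] >= min(expr[, "gB"]) & M[, "gB"] <= max(expr[, "gB"])))

  ## single-spot region: mean is the spot itself, variance is zero
  ds1 <- spatial_dataset(cbind(g1 = c(5, 1, 2)), cbind(c(0, 9, 9), c(0, 9, 10)),
                         c("solo", "b", "b"))
  w1 <- compute_kernel_weights(ds1, pairwise_distances(ds1))
  M1 <- estimate_spot_means(ds1, w1)
  V1 <- estimate_spot_variances(ds1, w1, M1)
  expect_equal(M1[1, 1], 5)
  expect_equal(V1[1, 1], 0)

  ## a constant gene triggers the degenerate-gene error at assembly time
  expect_error(assemble_wr_models(ds, ds$gene_ids, "a"), "degenerate")
})

test_that("estimates in one region ignore expression in another (masking)", {
  ds <- make_test_dataset(n = 24, m = 2, n_regions = 2, seed = 3)
  D <- pairwise_distances(ds)
  w <- compute_kernel_weights(ds, D)
  in_a <- ds$region_labels == "reg1"
  M1 <- estimate_spot_means(ds, w)
  ds2 <- ds
  ds2$expression[!in_a, ] <- 99 + ds2$expression[!in_a, ]
  M2 <- estimate_spot_means(ds2, w)
  expect_equal(M1[in_a, ], M2[in_a, ])
})

test_that("kernel estimates converge to region-wide moments as bandwidth grows", {
  ds <- make_test_dataset(n = 15, m = 2, n_regions = 1, seed = 5)
  w <- compute_kernel_weights(ds, pairwise_distances(ds),
                              kernel_config(bandwidth = 1e9))
  M <- estimate_spot_means(ds, w)
  V <- estimate_spot_variances(ds, w, M)
  ybar <- colMeans(ds$expression)
  vpop <- colMeans(sweep(ds$expression, 2, ybar)^2)
  for (i in 1:15) {
    expect_equal(unname(M[i, ]), unname(ybar), tolerance = 1e-6)
    expect_equal(unname(V[i, ]), unname(vpop), tolerance = 1e-6)
  }
})

test_that("region Pearson correlations match the textbook formula", {
  ds <- make_test_dataset(n = 30, m = 3, n_regions = 2, seed = 9)
  per <- estimate_region_correlations(ds, ds$gene_ids, "per-region")
  for (r in names(per)) {
    rows <- ds$region_labels == r
    expect_equal(unname(per[[r]]),
                 brute_pearson(ds$expression[rows, ]), tolerance = 1e-12)
    expect_equal(unname(diag(per[[r]])), rep(1, 3))
  }
  glob <- estimate_region_correlations(ds, ds$gene_ids, "global")
  expect_equal(unname(glob), brute_pearson(ds$expression), tolerance = 1e-12)
  pairs <- estimate_region_correlations(ds, ds$gene_ids, "region-pair")
  expect_named(pairs, "reg1|reg2")

  ## duplicated and negated genes give +1 / -1 off-diagonals
  Y <- cbind(a = rnorm(10), b = 0, c = 0)
  Y[, "b"] <- Y[, "a"]
  Y[, "c"] <- -Y[, "a"]
  dsd <- spatial_dataset(Y, cbind(1:10, 1), rep("r", 10))
  R <- estimate_region_correlations(dsd, dsd$gene_ids, "global")
  expect_equal(R["a", "b"], 1)
  expect_equal(R["a", "c"], -1)

  ## zero-variance gene names the gene and scope in the error
  dsz <- spatial_dataset(cbind(g1 = rnorm(10), g2 = 7), cbind(1:10, 1),
                         rep("myregion", 10))
  expect_error(estimate_region_correlations(dsz, dsz$gene_ids, "per-region"),
               "g2.*myregion|myregion.*g2")
})
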
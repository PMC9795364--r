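test_that("within-region permutation preserves per-region profile multisets", {
  ds <- make_test_dataset(n = 21, m = 3, n_regions = 3, seed = 71)
  set.seed(1)
  perm <- permute_within_regions(ds)
  expect_identical(perm$coordinates, ds$coordinates)
  expect_identical(perm$region_labels, ds$region_labels)
  for (r in unique(ds$region_labels)) {
    rows <- ds$region_labels == r
    orig <- unname(apply(ds$expression[rows, ], 1, paste, collapse = ","))
    shuf <- unname(apply(perm$expression[rows, ], 1, paste, collapse = ","))
    expect_setequal(shuf, orig)
  }

  ## single-spot regions cannot move
  ds1 <- spatial_dataset(cbind(g = 1:3), cbind(1:3, 1), c("a", "b", "c"))
  set.seed(2)
  expect_equal(permute_within_regions(ds1)$expression, ds1$expression)
})

test_that("BR permutation centers regions then shuffles residuals across scope", {
  ds <- make_test_dataset(n = 20, m = 2, n_regions = 2, seed = 73)
  centered <- spotcorr:::center_regions(ds$expression, ds$region_labels)
  for (r in unique(ds$region_labels)) {
    rows <- ds$region_labels == r
    expect_equal(unname(colMeans(centered[rows, ])), c(0, 0), tolerance = 1e-12)
  }
  set.seed(3)
  perm <- center_and_permute_residuals(ds)
  orig <- unname(apply(centered, 1, paste, collapse = ","))
  shuf <- unname(apply(perm$expression, 1, paste, collapse = ","))
  expect_setequal(shuf, orig)
})

test_that("SMC p values follow the sequential stopping rule", {
  queue_sampler <- function(values) {
    i <- 0
    function() {
      i <<- i + 1
      values[i]
    }
  }
  ## 20th exceedance on draw 400 -> p = 20/400
  vals <- c(rep(-1, 380), rep(1, 20))
  res <- smc_pvalue(0, queue_sampler(vals), smc_config(t = 20, g = 10000))
  expect_equal(res$p, 0.05)
  expect_equal(res$n_perm, 400)

  ## immediate termination: first 20 draws all exceed -> p = 1
  res2 <- smc_pvalue(0, queue_sampler(rep(1, 20)), smc_config())
  expect_equal(res2$p, 1)
  expect_equal(res2$n_perm, 20)

  ## cap reached with zero exceedances -> p = 1/g
  res3 <- smc_pvalue(0, queue_sampler(rep(-1, 99)),
                     smc_config(t = 20, g = 100))
  expect_equal(res3$p, 1 / 100)
  expect_equal(res3$n_perm, 99)

  ## ties count as exceedances (conservative)
  res4 <- smc_pvalue(0, queue_sampler(rep(0, 30)), smc_config())
  expect_equal(res4$p, 1)
})

test_that("Benjamini-Hochberg adjustment matches the hand step-up", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(rep(0.2, 4)), rep(0.2, 4))
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(5)
  p <- runif(25)
  expect_equal(benjamini_hochberg(p), brute_bh(p), tolerance = 1e-12)
})

test_that("test drivers are deterministic given a seed", {
  ds <- make_lattice_dataset(n_row = 8, n_col = 12, n_regions = 2, seed = 81,
                             corr = 0.3)
  cfg <- kernel_config(effective_neighbors_threshold = 5)
  a <- run_wr_test(ds, ds$gene_ids, cfg, smc_config(g = 200, seed = 99))
  b <- run_wr_test(ds, ds$gene_ids, cfg, smc_config(g = 200, seed = 99))
  expect_identical(a$table, b$table)
  ba <- run_br_test(ds, ds$gene_ids, cfg, smc_config(g = 200, seed = 98))
  bb <- run_br_test(ds, ds$gene_ids, cfg, smc_config(g = 200, seed = 98))
  expect_identical(ba$table, bb$table)
})

test_that("WR results cover surviving regions and error when none survive", {
  ds <- make_lattice_dataset(n_row = 8, n_col = 12, n_regions = 3, seed = 83)
  res <- run_wr_test(ds, ds$gene_ids, kernel_config(effective_neighbors_threshold = 5),
                     smc_config(g = 100, seed = 1))
  expect_setequal(res$table$scope, c("R1", "R2", "R3"))
  expect_true(all(res$table$p > 0 & res$table$p <= 1))
  expect_true(all(res$table$n_perm <= 99))
  expect_equal(res$table$q, benjamini_hochberg(res$table$p))

  tiny <- spatial_dataset(matrix(rnorm(8), 4, 2), cbind(c(1, 2, 40, 41), 1),
                          c("a", "a", "b", "b"))
  expect_error(run_wr_test(tiny, tiny$gene_ids), "filter")
})

test_that("BR screening excludes WR-significant regions and pairs combine", {
  ds <- make_lattice_dataset(n_row = 8, n_col = 18, n_regions = 3, seed = 85,
                             corr = 0.2)
  cfg <- kernel_config(effective_neighbors_threshold = 5)
  wr <- run_wr_test(ds, ds$gene_ids, cfg, smc_config(g = 200, seed = 7))
  ## force a fake screen: mark R2 as significant
  wr$table$q <- c(1, 0.001, 1)
  br <- run_br_test(ds, ds$gene_ids, cfg, smc_config(g = 200, seed = 8),
                    wr = wr)
  expect_identical(br$excluded_regions, "R2")
  expect_false(any(grepl("R2", br$table$scope)))
  expect_equal(nrow(br$table), 1L)  # only R1|R3 remains

  ## 3 surviving regions in pairwise mode -> choose(3, 2) rows
  br3 <- run_br_test(ds, ds$gene_ids, cfg, smc_config(g = 200, seed = 9))
  expect_equal(nrow(br3$table), 3L)
  expect_setequal(br3$table$scope, c("R1|R2", "R1|R3", "R2|R3"))

  ## all-regions mode gives a single statistic
  brall <- run_br_test(ds, ds$gene_ids, cfg, smc_config(g = 200, seed = 10),
                       mode = "all-regions")
  expect_equal(nrow(brall$table), 1L)

  ## every region screened out -> not testable
  wr$table$q <- c(0.001, 0.001, 0.001)
  expect_error(run_br_test(ds, ds$gene_ids, cfg, smc_config(g = 200), wr = wr),
               "not testable")
})

test_that("rank_gene_pairs enumerates unordered pairs sorted by p", {
  ds <- make_lattice_dataset(n_row = 8, n_col = 12, n_regions = 2, seed = 87,
                             m = 4)
  cfg <- kernel_config(effective_neighbors_threshold = 5)
  tab <- rank_gene_pairs(ds, ds$gene_ids, "wr", cfg,
                         smc_config(t = 5, g = 50, seed = 11))
  expect_equal(nrow(tab), choose(4, 2))
  expect_true(!is.unsorted(tab$p))
  expect_true(all(tab$gene_1 < tab$gene_2))

  tab2 <- rank_gene_pairs(ds, ds$gene_ids[1:2], "wr", cfg,
                          smc_config(t = 5, g = 50, seed = 12))
  expect_equal(nrow(tab2), 1L)
})

test_that("null simulations give approximately uniform WR p values", {
  ## i.i.d. Gaussian expression on a lattice: no spatial correlation
  ## structure, so region-level p values should be roughly uniform
  ps <- c()
  for (s in 1:12) {
    ds <- make_lattice_dataset(n_row = 10, n_col = 10, n_regions = 2,
                               seed = 900 + s)
    res <- run_wr_test(ds, ds$gene_ids,
                       kernel_config(effective_neighbors_threshold = 5),
                       smc_config(g = 500, seed = 950 + s))
    ps <- c(ps, res$table$p)
  }
  ## SMC p values are discrete, so KS ties are expected
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
  expect_lt(mean(ps < 0.1), 0.35)
})
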
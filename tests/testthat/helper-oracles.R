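## Independent brute-force implementations used as oracles. These are kept
## deliberately naive (double loops, textbook formulas) and must never call
## into the package's own estimation code paths.

make_test_dataset <- function(n = 20, m = 3, n_regions = 2, seed = 1) {
  set.seed(seed)
  coords <- cbind(runif(n, 0, 10), runif(n, 0, 10))
  expr <- matrix(rnorm(n * m), n, m,
                 dimnames = list(paste0("s", seq_len(n)),
                                 paste0("g", seq_len(m))))
  regions <- sort(rep_len(paste0("reg", seq_len(n_regions)), n))
  spatial_dataset(expr, coords, regions)
}

brute_kernel <- function(d, family, bw) {
  if (family == "gaussian") exp(-d / bw)
  else if (family == "triangular") max(1 - d / bw, 0)
  else as.numeric(d < bw)
}

brute_weights <- function(ds, D, family = "gaussian", bw = 5) {
  n <- length(ds$spot_ids)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (ds$region_labels[i] == ds$region_labels[j]) {
        W[i, j] <- brute_kernel(D[i, j], family, bw)
      }
    }
  }
  W
}

brute_means <- function(ds, W, genes) {
  Y <- ds$expression[, genes, drop = FALSE]
  n <- nrow(Y)
  M <- matrix(0, n, length(genes))
  for (i in seq_len(n)) {
    for (g in seq_along(genes)) {
      M[i, g] <- sum(W[i, ] * Y[, g]) / sum(W[i, ])
    }
  }
  M
}

brute_variances <- function(ds, W, M, genes) {
  Y <- ds$expression[, genes, drop = FALSE]
  n <- nrow(Y)
  V <- matrix(0, n, length(genes))
  for (i in seq_len(n)) {
    for (g in seq_along(genes)) {
      V[i, g] <- sum(W[i, ] * (Y[, g] - M[, g])^2) / sum(W[i, ])
    }
  }
  V
}

brute_covariances <- function(ds, W, M, genes) {
  Y <- ds$expression[, genes, drop = FALSE]
  n <- nrow(Y)
  m <- length(genes)
  A <- array(0, dim = c(n, m, m))
  for (i in seq_len(n)) {
    for (g in seq_len(m)) {
      for (h in seq_len(m)) {
        A[i, g, h] <- sum(W[i, ] * (Y[, g] - M[, g]) * (Y[, h] - M[, h])) /
          sum(W[i, ])
      }
    }
  }
  A
}

brute_pearson <- function(X) {
  m <- ncol(X)
  R <- diag(m)
  for (g in seq_len(m)) {
    for (h in seq_len(m)) {
      xg <- X[, g] - mean(X[, g])
      xh <- X[, h] - mean(X[, h])
      R[g, h] <- sum(xg * xh) / sqrt(sum(xg^2) * sum(xh^2))
    }
  }
  R
}

brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  sorted <- p[o] * n / seq_len(n)
  ## enforce step-up monotonicity from the largest p downwards
  for (i in rev(seq_len(n))) {
    q[i] <- if (i == n) min(sorted[i], 1) else min(sorted[i], q[i + 1])
  }
  out <- numeric(n)
  out[o] <- q
  out
}

brute_mvn_logdensity <- function(y, mu, sigma) {
  m <- length(y)
  r <- y - mu
  -0.5 * m * log(2 * pi) - 0.5 * log(det(sigma)) -
    0.5 * drop(t(r) %*% solve(sigma) %*% r)
}

## Textbook average-linkage agglomeration returning a k-cluster partition.
brute_average_linkage <- function(X, k) {
  n <- nrow(X)
  clusters <- as.list(seq_len(n))
  D <- as.matrix(dist(X))
  pair_dist <- function(a, b) mean(D[a, b])
  while (length(clusters) > k) {
    best <- c(NA, NA)
    best_d <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a < b) {
          d <- pair_dist(clusters[[a]], clusters[[b]])
          if (d < best_d) {
            best_d <- d
            best <- c(a, b)
          }
        }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  assign <- integer(n)
  for (ci in seq_along(clusters)) assign[clusters[[ci]]] <- ci
  assign
}

## Normalized partition signature so labelings can be compared up to
## renaming.
partition_signature <- function(assign) {
  paste(match(assign, unique(assign)), collapse = "-")
}

## Small lattice dataset with smoothly correlated Gaussian expression,
## used by permutation-level tests.
make_lattice_dataset <- function(n_row = 10, n_col = 12, n_regions = 2,
                                 m = 2, seed = 1, corr = 0) {
  set.seed(seed)
  coords <- cbind(x = rep(seq_len(n_col), each = n_row),
                  y = rep(seq_len(n_row), times = n_col))
  n <- nrow(coords)
  regions <- paste0("R", ceiling(coords[, "x"] / (n_col / n_regions)))
  Z <- matrix(rnorm(n * m), n, m)
  if (corr != 0 && m == 2) {
    Z[, 2] <- corr * Z[, 1] + sqrt(1 - corr^2) * Z[, 2]
  }
  colnames(Z) <- paste0("g", seq_len(m))
  spatial_dataset(Z, coords, regions)
}
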
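#' Multivariate normal log density
#'
#' Log density of an m-dimensional Gaussian evaluated via the Cholesky
#' factor of the covariance.
#'
#' @param y observation vector.
#' @param mu mean vector.
#' @param sigma symmetric positive-definite covariance matrix.
#' @param jitter nonnegative ridge added to the diagonal before
#'   factorization (default 0).
#' @return scalar log density.
#' @export
mvn_logdensity <- function(y, mu, sigma, jitter = 0) {
  m <- length(y)
  S <- sigma + diag(jitter, m)
  L <- tryCatch(chol(S), error = function(e) {
    stop("singular covariance in mvn_logdensity")
  })
  u <- backsolve(L, y - mu, transpose = TRUE)
  -0.5 * m * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(u * u)
}

## Correlation-scale statistic shared by WR and BR fast paths.
## Given standardized residuals U (n x m), a list of per-spot alternative
## correlations (rho columns) or a constant matrix, and a constant null
## correlation, T = sum_i [l_alt(i) - l_null(i)] where constants cancel.
corr_part_constant <- function(U, R, jitter = 1e-10) {
  m <- ncol(U)
  Rj <- R + diag(jitter, m)
  L <- tryCatch(chol(Rj), error = function(e) {
    stop("singular covariance in likelihood-ratio statistic")
  })
  W <- t(backsolve(L, t(U), transpose = TRUE))
  -nrow(U) * sum(log(diag(L))) - 0.5 * sum(W * W)
}

#' Assemble WR-test covariance models
#'
#' Builds the null and alternative spot-wise covariance models for the
#' within-region test on one region. Both models share the kernel means
#' and kernel variances (diagonals), so the likelihood ratio isolates
#' correlation: the null model's off-diagonals come from the region-wide
#' Pearson correlation scaled by the kernel standard deviations, while the
#' alternative model uses the full kernel covariance at each spot.
#'
#' @param dataset a (filtered) `spatial_dataset`.
#' @param geneset genes (ids or [gene_set()]).
#' @param region region label to test.
#' @param config a [kernel_config()].
#' @param provider a [distance_provider()].
#' @return list with `null` and `alt`, each a covariance model: list with
#'   `means` (n_r-by-m), `covariances` (n_r, m, m array), `label`, and the
#'   region spot ids.
#' @export
assemble_wr_models <- function(dataset, geneset, region,
                               config = kernel_config(),
                               provider = distance_provider()) {
  genes <- resolve_genes(dataset, geneset)
  rows <- which(dataset$region_labels == region)
  if (length(rows) < 3L) stop(sprintf("region '%s' has fewer than 3 spots", region))
  sub <- dataset[rows]
  D <- pairwise_distances(sub, provider)
  w <- compute_kernel_weights(sub, D, config)
  M <- estimate_spot_means(sub, w, genes)
  V <- estimate_spot_variances(sub, w, M, genes)
  check_degenerate(V, genes, sprintf("region '%s'", region))
  A <- estimate_spot_covariances(sub, w, M, genes)
  for (g in seq_along(genes)) A[, g, g] <- V[, g]
  RC <- estimate_region_correlations(sub, genes, "global")
  m <- length(genes)
  n_r <- length(rows)
  Sd <- sqrt(V)
  null_cov <- array(0, dim = dim(A), dimnames = dimnames(A))
  for (g in seq_len(m)) {
    for (h in seq_len(m)) {
      null_cov[, g, h] <- RC[g, h] * Sd[, g] * Sd[, h]
    }
  }
  list(
    null = list(means = M, covariances = null_cov, label = "wr_null",
                spot_ids = sub$spot_ids),
    alt = list(means = M, covariances = A, label = "wr_alt",
               spot_ids = sub$spot_ids)
  )
}

#' Assemble BR-test covariance models
#'
#' Builds the null and alternative spot-wise covariance models for the
#' between-region test over a scope (a pair of regions or all regions).
#' The alternative model gives every spot its own region's Pearson
#' correlation; the null model gives every spot the Pearson correlation
#' pooled over the whole scope. Diagonals are the kernel variances in both.
#'
#' @param dataset a (filtered) `spatial_dataset`.
#' @param geneset genes.
#' @param scope character vector of region labels (length >= 2), or
#'   `"all"` for every region.
#' @param config a [kernel_config()].
#' @param provider a [distance_provider()].
#' @return list with `null` and `alt` covariance models over the scope
#'   spots (ordered as in the dataset).
#' @export
assemble_br_models <- function(dataset, geneset, scope = "all",
                               config = kernel_config(),
                               provider = distance_provider()) {
  genes <- resolve_genes(dataset, geneset)
  if (identical(scope, "all")) scope <- sort(unique(dataset$region_labels))
  rows <- which(dataset$region_labels %in% scope)
  sub <- dataset[rows]
  D <- pairwise_distances(sub, provider)
  w <- compute_kernel_weights(sub, D, config)
  M <- estimate_spot_means(sub, w, genes)
  V <- estimate_spot_variances(sub, w, M, genes)
  check_degenerate(V, genes, paste0("scope ", paste(scope, collapse = "|")))
  per_region <- estimate_region_correlations(sub, genes, "per-region")
  R_pool <- estimate_region_correlations(sub, genes, "global")
  m <- length(genes)
  Sd <- sqrt(V)
  mk_cov <- function(R_of_spot) {
    out <- array(0, dim = c(length(rows), m, m),
                 dimnames = list(sub$spot_ids, genes, genes))
    for (g in seq_len(m)) {
      for (h in seq_len(m)) {
        out[, g, h] <- R_of_spot[, g, h] * Sd[, g] * Sd[, h]
      }
    }
    out
  }
  R_alt <- array(0, dim = c(length(rows), m, m))
  for (r in names(per_region)) {
    idx <- which(sub$region_labels == r)
    for (g in seq_len(m)) for (h in seq_len(m)) {
      R_alt[idx, g, h] <- per_region[[r]][g, h]
    }
  }
  R_null <- array(rep(R_pool, each = length(rows)), dim = c(length(rows), m, m))
  list(
    null = list(means = M, covariances = mk_cov(R_null), label = "br_null",
                spot_ids = sub$spot_ids),
    alt = list(means = M, covariances = mk_cov(R_alt), label = "br_alt",
               spot_ids = sub$spot_ids)
  )
}

#' Likelihood-ratio statistic between two covariance models
#'
#' T(Y) is the sum over scope spots of the difference between the MVN log
#' densities of the observation under the alternative and null models.
#' Identical models give exactly T = 0.
#'
#' @param dataset a `spatial_dataset` containing the scope spots.
#' @param null,alt covariance models from [assemble_wr_models()] or
#'   [assemble_br_models()].
#' @param geneset genes the models were built for.
#' @param jitter diagonal ridge applied to both models' covariances.
#' @return list with `value` (T), `scope_spots`, `n_spots`.
#' @export
likelihood_ratio_statistic <- function(dataset, null, alt, geneset,
                                       jitter = 0) {
  genes <- resolve_genes(dataset, geneset)
  if (!identical(null$spot_ids, alt$spot_ids)) {
    stop("null and alternative models cover different spot sets")
  }
  rows <- match(null$spot_ids, dataset$spot_ids)
  Y <- dataset$expression[rows, genes, drop = FALSE]
  total <- 0
  for (i in seq_along(rows)) {
    total <- total +
      mvn_logdensity(Y[i, ], alt$means[i, ], alt$covariances[i, , ], jitter) -
      mvn_logdensity(Y[i, ], null$means[i, ], null$covariances[i, , ], jitter)
  }
  list(value = total, scope_spots = null$spot_ids, n_spots = length(rows))
}

## ---- fast statistic paths used by the permutation drivers ----

## WR statistic for one region given the expression block Y (n_r x m), the
## row-normalized within-region weight matrix Wn, and optionally a frozen
## null correlation factor (the region Pearson correlation is invariant
## under within-region row permutation, so drivers precompute it).
wr_stat_fast <- function(Y, Wn, R_null = NULL, jitter = 1e-10) {
  mom <- kernel_moments(Y, Wn)
  V <- mom$variances
  if (any(V <= 0)) stop("degenerate gene (zero kernel variance) in WR statistic")
  U <- mom$resid / sqrt(V)
  idx <- mom$pair_idx
  rho <- mom$pair_cov / (sqrt(V[, idx[, 1], drop = FALSE]) *
                           sqrt(V[, idx[, 2], drop = FALSE]))
  if (is.null(R_null)) R_null <- stats::cor(Y)
  alt <- sum_corr_loglik(U, rho, jitter)
  null <- corr_part_constant(U, R_null, jitter)
  alt - null
}

## BR statistic over a scope given the expression block Y, region labels,
## per-region row indices and row-normalized weights, and optionally a
## frozen pooled correlation (invariant under cross-scope row permutation
## of centered residuals, so drivers precompute it for the null draws).
br_stat_fast <- function(Y, region_rows, Wn_list, R_pool = NULL,
                         jitter = 1e-10) {
  if (is.null(R_pool)) R_pool <- stats::cor(Y)
  m <- ncol(Y)
  total <- 0
  for (r in names(region_rows)) {
    rows <- region_rows[[r]]
    Yr <- Y[rows, , drop = FALSE]
    mom <- kernel_moments(Yr, Wn_list[[r]])
    V <- mom$variances
    if (any(V <= 0)) stop("degenerate gene (zero kernel variance) in BR statistic")
    U <- mom$resid / sqrt(V)
    Rr <- stats::cor(Yr)
    total <- total + corr_part_constant(U, Rr, jitter) -
      corr_part_constant(U, R_pool, jitter)
  }
  total
}
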
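#' Spatial kernel configuration
#'
#' Controls the region-masked spatial weighting used by all spot-level
#' estimates. Three unnormalized kernel families are supported: gaussian
#' `exp(-D/bandwidth)` (note the *unsquared* distance), triangular
#' `max(1 - D/bandwidth, 0)` and uniform `1[D < bandwidth]`. The default
#' bandwidth of 5 is calibrated to 10x Visium array row/column coordinates;
#' spots whose kernel-weight sum ("effective neighbors") falls below
#' `effective_neighbors_threshold` are dropped by [filter_spots()] because
#' their estimates would rest on too small an effective sample.
#'
#' @param family kernel family.
#' @param bandwidth positive decay scale, in the units of the spot
#'   coordinates.
#' @param effective_neighbors_threshold nonnegative filtering threshold
#'   (default 10).
#' @return object of class `kernel_config`.
#' @export
kernel_config <- function(family = c("gaussian", "triangular", "uniform"),
                          bandwidth = 5,
                          effective_neighbors_threshold = 10) {
  family <- match.arg(family)
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L || bandwidth <= 0) {
    stop("invalid kernel config: bandwidth must be a positive scalar")
  }
  if (effective_neighbors_threshold < 0) {
    stop("invalid kernel config: effective_neighbors_threshold must be >= 0")
  }
  structure(list(family = family, bandwidth = bandwidth,
                 effective_neighbors_threshold = effective_neighbors_threshold),
            class = "kernel_config")
}

#' Evaluate a spatial kernel
#'
#' @param distance nonnegative distance(s).
#' @param family `"gaussian"`, `"triangular"` or `"uniform"`.
#' @param bandwidth positive scalar.
#' @return kernel weight(s) in `[0, 1]`.
#' @export
kernel_function <- function(distance,
                            family = c("gaussian", "triangular", "uniform"),
                            bandwidth = 5) {
  family <- match.arg(family)
  if (bandwidth <= 0) stop("invalid kernel config: bandwidth must be positive")
  switch(family,
    gaussian = exp(-distance / bandwidth),
    triangular = pmax(1 - distance / bandwidth, 0),
    uniform = (distance < bandwidth) * 1
  )
}

#' Region-masked kernel weights
#'
#' Computes the n-by-n weight matrix with entry (i, j) equal to
#' `1[region_i == region_j] * K(d_ij)`, together with each spot's effective
#' neighbor count (its row sum). A spot always carries weight 1 for itself,
#' so effective neighbors are at least 1.
#'
#' @param dataset a `spatial_dataset`.
#' @param distances n-by-n distance matrix from [pairwise_distances()].
#' @param config a [kernel_config()].
#' @return object of class `kernel_weights`: list with `weights` (n-by-n)
#'   and `effective_neighbors` (length n).
#' @export
compute_kernel_weights <- function(dataset, distances, config = kernel_config()) {
  n <- nrow(dataset$expression)
  if (!all(dim(distances) == c(n, n))) {
    stop("distance matrix shape does not match dataset")
  }
  W <- kernel_function(distances, config$family, config$bandwidth)
  same <- outer(dataset$region_labels, dataset$region_labels, "==")
  W[!same] <- 0
  structure(list(weights = W, effective_neighbors = rowSums(W)),
            class = "kernel_weights")
}

#' Filter spots with too few effective neighbors
#'
#' Spot-level kernel estimates are unstable when few same-region spots fall
#' within the kernel's reach. Spots with effective neighbors below the
#' threshold are removed. Because removal changes every remaining spot's
#' neighborhood, kernel weights must be recomputed on the filtered dataset
#' before any estimation; [prepare_dataset()] does this.
#'
#' @param dataset a `spatial_dataset`.
#' @param weights a `kernel_weights` computed on `dataset`.
#' @param threshold nonnegative effective-neighbors cutoff (default 10).
#' @return list with `dataset` (the filtered `spatial_dataset`) and `kept`
#'   (logical mask over the input spots).
#' @export
filter_spots <- function(dataset, weights, threshold = 10) {
  if (threshold < 0) stop("threshold must be >= 0")
  kept <- weights$effective_neighbors >= threshold
  if (!any(kept)) {
    stop(sprintf(
      "all spots removed by the effective-neighbors filter (threshold %g)",
      threshold))
  }
  list(dataset = dataset[kept], kept = kept)
}

#' Filter a dataset and recompute kernel weights
#'
#' Convenience wrapper: computes distances and kernel weights, applies the
#' effective-neighbors filter, and recomputes weights on the surviving
#' spots (single-pass filtering).
#'
#' @param dataset a `spatial_dataset`.
#' @param config a [kernel_config()].
#' @param provider a [distance_provider()].
#' @return list with `dataset`, `weights` (recomputed), `distances`
#'   (filtered) and `kept`.
#' @export
prepare_dataset <- function(dataset, config = kernel_config(),
                            provider = distance_provider()) {
  D <- pairwise_distances(dataset, provider)
  w0 <- compute_kernel_weights(dataset, D, config)
  f <- filter_spots(dataset, w0, config$effective_neighbors_threshold)
  Dk <- D[f$kept, f$kept, drop = FALSE]
  w <- compute_kernel_weights(f$dataset, Dk, config)
  list(dataset = f$dataset, weights = w, distances = Dk, kept = f$kept)
}

## Row-normalized weights: each row i is the convex weight vector over
## contributing spots j used by all kernel estimates at spot i.
normalize_weights <- function(weights) {
  weights$weights / weights$effective_neighbors
}

#' Kernel estimates of spot-level means
#'
#' For each spot, the kernel-weighted average of expression over spots in
#' the same region (self included): a convex combination, so estimates are
#' bounded by the same-region per-gene range.
#'
#' @param dataset a `spatial_dataset`.
#' @param weights `kernel_weights` computed on `dataset`.
#' @param geneset genes to estimate (gene ids or a [gene_set()]); defaults
#'   to all genes.
#' @return n-by-|geneset| matrix of means.
#' @export
estimate_spot_means <- function(dataset, weights, geneset = dataset$gene_ids) {
  genes <- resolve_genes(dataset, geneset)
  Wn <- normalize_weights(weights)
  Wn %*% dataset$expression[, genes, drop = FALSE]
}

#' Kernel estimates of spot-level variances
#'
#' Kernel-weighted average of squared residuals, where each contributing
#' spot's residual is taken about *its own* kernel mean.
#'
#' @inheritParams estimate_spot_means
#' @param means matrix from [estimate_spot_means()] for the same genes.
#' @return n-by-|geneset| matrix of nonnegative variances.
#' @export
estimate_spot_variances <- function(dataset, weights, means,
                                    geneset = dataset$gene_ids) {
  genes <- resolve_genes(dataset, geneset)
  Wn <- normalize_weights(weights)
  R <- dataset$expression[, genes, drop = FALSE] - means
  Wn %*% (R * R)
}

#' Kernel estimates of spot-level covariance matrices
#'
#' Kernel-weighted average of residual outer products; returns one
#' symmetric positive semidefinite matrix per spot. The diagonal equals
#' [estimate_spot_variances()] computed from the same weights and means.
#'
#' @inheritParams estimate_spot_variances
#' @return array of dimension (n, m, m) with `m = length(geneset)`.
#' @export
estimate_spot_covariances <- function(dataset, weights, means,
                                      geneset = dataset$gene_ids) {
  genes <- resolve_genes(dataset, geneset)
  m <- length(genes)
  n <- nrow(dataset$expression)
  Wn <- normalize_weights(weights)
  R <- dataset$expression[, genes, drop = FALSE] - means
  ## all m(m+1)/2 residual cross-products in one BLAS call
  idx <- which(upper.tri(diag(m), diag = TRUE), arr.ind = TRUE)
  P <- R[, idx[, 1], drop = FALSE] * R[, idx[, 2], drop = FALSE]
  S <- Wn %*% P
  out <- array(0, dim = c(n, m, m), dimnames = list(dataset$spot_ids, genes, genes))
  for (k in seq_len(nrow(idx))) {
    out[, idx[k, 1], idx[k, 2]] <- S[, k]
    out[, idx[k, 2], idx[k, 1]] <- S[, k]
  }
  out
}

## Internal fast path: returns list(means, variances, pair covariances as
## n x npair matrix in upper.tri order) from a row-normalized weight matrix.
kernel_moments <- function(Y, Wn) {
  m <- ncol(Y)
  M <- Wn %*% Y
  R <- Y - M
  V <- Wn %*% (R * R)
  if (m >= 2L) {
    idx <- which(upper.tri(diag(m)), arr.ind = TRUE)
    P <- R[, idx[, 1], drop = FALSE] * R[, idx[, 2], drop = FALSE]
    C <- Wn %*% P
  } else {
    idx <- NULL
    C <- NULL
  }
  list(means = M, resid = R, variances = V, pair_cov = C, pair_idx = idx)
}

check_degenerate <- function(V, genes, where = "kernel estimate") {
  bad <- which(V <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    g <- unique(genes[bad[, 2]])
    stop(sprintf("degenerate gene (zero variance) in %s: %s",
                 where, paste(g, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Region-level Pearson correlation matrices
#'
#' Estimates, per requested scope, the ordinary Pearson correlation matrix
#' of the gene set over all spots in that scope: each region separately,
#' each unordered region pair pooled, or the whole slide.
#'
#' @param dataset a `spatial_dataset`.
#' @param geneset genes (ids or [gene_set()]).
#' @param scope `"per-region"`, `"region-pair"` or `"global"`.
#' @return for `"per-region"` a named list of correlation matrices; for
#'   `"region-pair"` a named list keyed `"A|B"`; for `"global"` a single
#'   matrix.
#' @export
estimate_region_correlations <- function(dataset, geneset,
                                         scope = c("per-region", "region-pair",
                                                   "global")) {
  scope <- match.arg(scope)
  genes <- resolve_genes(dataset, geneset)
  Y <- dataset$expression[, genes, drop = FALSE]
  corr_of <- function(rows, label) {
    if (length(rows) < 3L) {
      stop(sprintf("scope '%s' has fewer than 3 spots", label))
    }
    sub <- Y[rows, , drop = FALSE]
    sds <- apply(sub, 2, stats::sd)
    if (any(sds == 0)) {
      stop(sprintf("degenerate gene (zero variance) in scope '%s': %s",
                   label, paste(genes[sds == 0], collapse = ", ")))
    }
    stats::cor(sub)
  }
  regions <- sort(unique(dataset$region_labels))
  if (scope == "per-region") {
    out <- lapply(regions, function(r) {
      corr_of(which(dataset$region_labels == r), r)
    })
    names(out) <- regions
    out
  } else if (scope == "region-pair") {
    pairs <- utils::combn(regions, 2, simplify = FALSE)
    out <- lapply(pairs, function(p) {
      corr_of(which(dataset$region_labels %in% p), paste(p, collapse = "|"))
    })
    names(out) <- vapply(pairs, paste, "", collapse = "|")
    out
  } else {
    corr_of(seq_along(dataset$region_labels), "global")
  }
}
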
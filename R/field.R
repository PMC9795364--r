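#' Spot-wise kernel correlation field for a gene pair
#'
#' Estimates the correlation between two genes at every surviving spot as
#' the ratio of the kernel covariance to the product of kernel standard
#' deviations, clipped to `[-1, 1]`.
#'
#' @param dataset a `spatial_dataset`.
#' @param pair character vector of two gene ids.
#' @param kernel a [kernel_config()].
#' @param provider a [distance_provider()].
#' @return object of class `correlation_field`: list with `values`
#'   (named per-spot correlations), `spot_ids`, `coordinates`,
#'   `region_labels`, `pair`, and optional `ci_lower`/`ci_upper`.
#' @export
correlation_field <- function(dataset, pair, kernel = kernel_config(),
                              provider = distance_provider()) {
  genes <- resolve_genes(dataset, pair)
  if (length(genes) != 2L) stop("pair must name exactly 2 genes")
  prep <- prepare_dataset(dataset, kernel, provider)
  ds <- prep$dataset
  w <- prep$weights
  M <- estimate_spot_means(ds, w, genes)
  V <- estimate_spot_variances(ds, w, M, genes)
  check_degenerate(V, genes, "correlation field")
  Wn <- normalize_weights(w)
  R <- ds$expression[, genes, drop = FALSE] - M
  cv <- drop(Wn %*% (R[, 1] * R[, 2]))
  vals <- pmin(pmax(cv / sqrt(V[, 1] * V[, 2]), -1), 1)
  names(vals) <- ds$spot_ids
  structure(list(values = vals, spot_ids = ds$spot_ids,
                 coordinates = ds$coordinates,
                 region_labels = ds$region_labels,
                 pair = genes, kernel_config = kernel),
            class = "correlation_field")
}

#' @export
print.correlation_field <- function(x, ...) {
  cat(sprintf("correlation_field %s ~ %s over %d spots; range [%.3f, %.3f]\n",
              x$pair[1], x$pair[2], length(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Plot a correlation field over the slide
#'
#' @param x a `correlation_field`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.correlation_field <- function(x, ...) {
  if (is.null(x$coordinates)) stop("field has no coordinates to plot")
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(101)
  idx <- round((x$values + 1) / 2 * 100) + 1
  graphics::plot(x$coordinates[, 1], x$coordinates[, 2], col = pal[idx],
                 pch = 15, xlab = "x", ylab = "y",
                 main = paste(x$pair, collapse = " ~ "), ...)
  invisible(x)
}

#' Bootstrap confidence interval for a spot's correlation estimate
#'
#' Resamples, with replacement, the spots of the focal spot's neighborhood
#' (same region, distance at most `radius`) and recomputes the kernel
#' correlation estimate at the focal spot for each resample; the interval
#' is the empirical percentile interval of the bootstrap estimates.
#'
#' @param dataset a `spatial_dataset`.
#' @param pair two gene ids.
#' @param spot focal spot id (or index).
#' @param radius neighborhood radius; defaults to twice the kernel
#'   bandwidth.
#' @param B number of bootstrap resamples.
#' @param level confidence level in (0, 1).
#' @param kernel a [kernel_config()].
#' @param provider a [distance_provider()].
#' @return list with `estimate`, `lower`, `upper`, `n_neighborhood`.
#' @export
bootstrap_correlation_ci <- function(dataset, pair, spot, radius = NULL,
                                     B = 500, level = 0.9,
                                     kernel = kernel_config(),
                                     provider = distance_provider()) {
  genes <- resolve_genes(dataset, pair)
  if (length(genes) != 2L) stop("pair must name exactly 2 genes")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (is.null(radius)) radius <- 2 * kernel$bandwidth
  if (radius <= 0) stop("radius must be positive")
  if (is.character(spot)) spot <- match(spot, dataset$spot_ids)
  D <- pairwise_distances(dataset, provider)
  same <- dataset$region_labels == dataset$region_labels[spot]
  nb <- which(same & D[spot, ] <= radius)
  if (length(nb) < 3L) {
    stop("neighborhood too small to estimate a bootstrap interval (need >= 3 spots)")
  }
  kw <- kernel_function(D[spot, nb], kernel$family, kernel$bandwidth)
  Y <- dataset$expression[nb, genes, drop = FALSE]
  est_at <- function(idx) {
    w <- kw[idx]
    sw <- sum(w)
    mu <- colSums(Y[idx, , drop = FALSE] * w) / sw
    r1 <- Y[idx, 1] - mu[1]
    r2 <- Y[idx, 2] - mu[2]
    v1 <- sum(w * r1 * r1) / sw
    v2 <- sum(w * r2 * r2) / sw
    if (v1 <= 0 || v2 <= 0) return(NA_real_)
    min(max(sum(w * r1 * r2) / sw / sqrt(v1 * v2), -1), 1)
  }
  estimate <- est_at(seq_along(nb))
  boots <- vapply(seq_len(B), function(b) {
    est_at(sample(length(nb), replace = TRUE))
  }, 0)
  boots <- boots[is.finite(boots)]
  qs <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  list(estimate = estimate, lower = qs[1], upper = qs[2],
       n_neighborhood = length(nb))
}

#' Cluster gene pairs by their spatial correlation pattern
#'
#' Groups gene pairs whose spot-wise correlation estimates follow similar
#' spatial patterns, using hierarchical agglomerative clustering (Euclidean
#' distance, average linkage by default) of the per-pair correlation
#' vectors. All fields must be computed over the same spot set.
#'
#' @param fields list of [correlation_field()] objects.
#' @param n_clusters number of subgroups (cut the tree at this count), or
#'   `NULL` to use `cut_height`.
#' @param cut_height dendrogram cut height, used when `n_clusters` is
#'   `NULL`.
#' @param method linkage method for [stats::hclust()].
#' @return list with `assignments` (named integer vector, one entry per
#'   pair) and `tree` (the `hclust` object).
#' @export
cluster_pair_patterns <- function(fields, n_clusters = NULL,
                                  cut_height = NULL, method = "average") {
  if (length(fields) < 2L) stop("need at least 2 correlation fields")
  ids <- fields[[1]]$spot_ids
  for (f in fields) {
    if (!identical(f$spot_ids, ids)) {
      stop("correlation fields cover different spot sets")
    }
  }
  X <- do.call(rbind, lapply(fields, function(f) f$values))
  rownames(X) <- vapply(fields, function(f) paste(f$pair, collapse = "~"), "")
  tree <- stats::hclust(stats::dist(X), method = method)
  assignments <- if (!is.null(n_clusters)) {
    stats::cutree(tree, k = n_clusters)
  } else if (!is.null(cut_height)) {
    stats::cutree(tree, h = cut_height)
  } else {
    stop("provide n_clusters or cut_height")
  }
  list(assignments = assignments, tree = tree)
}
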
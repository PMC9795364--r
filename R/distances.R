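#' Spot-spot distance provider
#'
#' The testing kernel operates on an arbitrary spot-spot distance. In
#' `euclidean` mode distances are computed from the dataset's coordinates
#' (the usual case for slide data); in `precomputed` mode any symmetric
#' nonnegative matrix with zero diagonal is accepted — e.g. shortest-path
#' distances along a nearest-neighbors graph of cells, which need not obey
#' the triangle inequality restrictions of a metric embedding.
#'
#' @param mode `"euclidean"` or `"precomputed"`.
#' @param distances n-by-n matrix, required for `"precomputed"`.
#' @return object of class `distance_provider`.
#' @export
distance_provider <- function(mode = c("euclidean", "precomputed"),
                              distances = NULL) {
  mode <- match.arg(mode)
  if (mode == "precomputed") {
    if (is.null(distances)) stop("precomputed mode requires a distance matrix")
    distances <- as.matrix(distances)
    if (nrow(distances) != ncol(distances)) {
      stop("invalid distances: matrix must be square")
    }
    if (any(distances < 0)) stop("invalid distances: negative entries")
    if (max(abs(distances - t(distances))) > 1e-8) {
      stop("invalid distances: matrix must be symmetric")
    }
    if (any(abs(diag(distances)) > 1e-12)) {
      stop("invalid distances: diagonal must be zero")
    }
  }
  structure(list(mode = mode, distances = distances),
            class = "distance_provider")
}

#' Pairwise spot-spot distances
#'
#' @param dataset a `spatial_dataset`.
#' @param provider a [distance_provider()]; defaults to Euclidean distances
#'   on the dataset's coordinates.
#' @return symmetric n-by-n matrix of nonnegative distances with zero
#'   diagonal.
#' @export
pairwise_distances <- function(dataset, provider = distance_provider()) {
  n <- nrow(dataset$expression)
  if (provider$mode == "precomputed") {
    D <- provider$distances
    if (nrow(D) != n) stop("precomputed distance matrix does not match dataset size")
    return(D)
  }
  if (is.null(dataset$coordinates)) {
    stop("euclidean mode requires coordinates")
  }
  D <- as.matrix(stats::dist(dataset$coordinates))
  dimnames(D) <- list(dataset$spot_ids, dataset$spot_ids)
  D
}
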
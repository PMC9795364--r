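#' Construct a spatial expression dataset
#'
#' Bundles a spot-by-gene expression matrix with spot coordinates and a
#' per-spot tissue-region label. The testing functions expect `expression`
#' on a normalized (roughly continuous) scale, not raw counts; the
#' simulator returns counts and [normalize_logcpm()] provides a log-CPM
#' fallback normalization.
#'
#' @param expression numeric matrix, spots in rows, genes in columns.
#' @param coordinates numeric matrix with one row per spot (2 columns for a
#'   slide; any dimension is accepted, and it may be `NULL` when a
#'   precomputed spot-spot distance matrix is supplied to
#'   [pairwise_distances()]).
#' @param region_labels character or factor of length `nrow(expression)`
#'   assigning each spot to a tissue region. Labels are opaque: no ordering
#'   is assumed.
#' @param spot_ids,gene_ids optional identifier vectors; default to the
#'   dimnames of `expression` or generated ids.
#' @param size_factors optional positive per-spot exposures (total UMI
#'   counts); carried along for simulation and normalization.
#'
#' @return An object of class `spatial_dataset`: a list with elements
#'   `expression`, `coordinates`, `region_labels`, `spot_ids`, `gene_ids`
#'   and `size_factors`.
#' @seealso [validate_dataset()], [run_wr_test()], [run_br_test()]
#' @export
spatial_dataset <- function(expression, coordinates = NULL, region_labels,
                            spot_ids = NULL, gene_ids = NULL,
                            size_factors = NULL) {
  expression <- as.matrix(expression)
  storage.mode(expression) <- "double"
  n <- nrow(expression)
  if (is.null(spot_ids)) {
    spot_ids <- rownames(expression)
    if (is.null(spot_ids)) spot_ids <- paste0("spot_", seq_len(n))
  }
  if (is.null(gene_ids)) {
    gene_ids <- colnames(expression)
    if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(expression)))
  }
  rownames(expression) <- spot_ids
  colnames(expression) <- gene_ids
  if (!is.null(coordinates)) {
    coordinates <- as.matrix(coordinates)
    storage.mode(coordinates) <- "double"
    rownames(coordinates) <- spot_ids
  }
  region_levels <- if (is.factor(region_labels)) {
    levels(region_labels)
  } else {
    unique(as.character(region_labels))
  }
  structure(
    list(
      expression = expression,
      coordinates = coordinates,
      region_labels = as.character(region_labels),
      region_levels = region_levels,
      spot_ids = as.character(spot_ids),
      gene_ids = as.character(gene_ids),
      size_factors = size_factors
    ),
    class = "spatial_dataset"
  )
}

#' Validate a spatial dataset
#'
#' Checks the structural invariants of a [spatial_dataset()] and reports
#' violations as a character vector of diagnostics, one entry per problem.
#' Unlike an error, diagnostics let a caller inspect all problems at once;
#' an empty character vector means the dataset is consistent. The input is
#' never modified.
#'
#' @param dataset a `spatial_dataset`.
#' @return character vector of diagnostic messages (empty if valid).
#' @export
validate_dataset <- function(dataset) {
  diags <- character(0)
  n <- nrow(dataset$expression)
  m <- ncol(dataset$expression)
  if (n < 1L) diags <- c(diags, "expression matrix has no spots (n >= 1 required)")
  if (m < 1L) diags <- c(diags, "expression matrix has no genes (m >= 1 required)")
  if (length(dataset$region_labels) != n) {
    diags <- c(diags, sprintf(
      "region_labels length (%d) does not match number of spots (%d)",
      length(dataset$region_labels), n))
  }
  if (!is.null(dataset$coordinates) && nrow(dataset$coordinates) != n) {
    diags <- c(diags, sprintf(
      "coordinates rows (%d) do not match number of spots (%d)",
      nrow(dataset$coordinates), n))
  }
  if (length(dataset$spot_ids) != n) {
    diags <- c(diags, "spot_ids length does not match number of spots")
  }
  if (length(dataset$gene_ids) != m) {
    diags <- c(diags, "gene_ids length does not match number of genes")
  }
  if (anyDuplicated(dataset$spot_ids)) {
    diags <- c(diags, "duplicated spot_ids")
  }
  if (!all(is.finite(dataset$expression))) {
    diags <- c(diags, "expression contains non-finite values")
  }
  if (!is.null(dataset$region_levels)) {
    empty <- setdiff(dataset$region_levels, dataset$region_labels)
    if (length(empty)) {
      diags <- c(diags, paste0("region label with zero spots: ",
                               paste(empty, collapse = ", ")))
    }
  }
  if (!is.null(dataset$size_factors)) {
    if (length(dataset$size_factors) != n) {
      diags <- c(diags, "size_factors length does not match number of spots")
    } else if (any(!is.finite(dataset$size_factors) | dataset$size_factors <= 0)) {
      diags <- c(diags, "size_factors must be finite and positive")
    }
  }
  diags
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat("spatial_dataset:", nrow(x$expression), "spots x",
      ncol(x$expression), "genes\n")
  cat("  regions:", paste(names(table(x$region_labels)), collapse = ", "), "\n")
  if (!is.null(x$coordinates)) {
    cat("  coordinates:", ncol(x$coordinates), "dimensions\n")
  } else {
    cat("  coordinates: none (precomputed distances expected)\n")
  }
  invisible(x)
}

#' Subset a spatial dataset by spots
#'
#' @param x a `spatial_dataset`.
#' @param i spot index (logical, integer or spot-id character vector).
#' @param ... ignored.
#' @return a `spatial_dataset` restricted to the selected spots.
#' @export
`[.spatial_dataset` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$spot_ids)
  spatial_dataset(
    expression = x$expression[i, , drop = FALSE],
    coordinates = if (is.null(x$coordinates)) NULL else x$coordinates[i, , drop = FALSE],
    region_labels = x$region_labels[i],
    spot_ids = x$spot_ids[i],
    gene_ids = x$gene_ids,
    size_factors = if (is.null(x$size_factors)) NULL else x$size_factors[i]
  )
}

#' Define a gene set
#'
#' @param name set identifier.
#' @param genes ordered character vector of at least two gene ids;
#'   duplicates are dropped with a warning.
#' @return object of class `gene_set` with elements `name` and `genes`.
#' @export
gene_set <- function(name, genes) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) {
    warning(sprintf("gene set '%s': dropping duplicated members", name))
    genes <- unique(genes)
  }
  structure(list(name = as.character(name), genes = genes),
            class = "gene_set")
}

## Resolve a geneset argument (gene_set object or character vector) against
## a dataset; errors on genes absent from the dataset.
resolve_genes <- function(dataset, geneset) {
  genes <- if (inherits(geneset, "gene_set")) geneset$genes else as.character(geneset)
  missing <- setdiff(genes, dataset$gene_ids)
  if (length(missing)) {
    stop("genes not present in dataset: ", paste(missing, collapse = ", "))
  }
  genes
}

geneset_name <- function(geneset) {
  if (inherits(geneset, "gene_set")) geneset$name else paste(geneset, collapse = "+")
}
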
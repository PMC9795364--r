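#' Read an expression matrix
#'
#' Two on-disk layouts are supported: `dense_tsv`, a tab-separated table
#' with spots as rows (index column of spot ids, header row of gene ids);
#' and `mtx_triplet`, a directory holding `matrix.mtx` (MatrixMarket
#' coordinate format, genes-by-spots as written by 10x-style pipelines)
#' with `barcodes.tsv` (spot ids) and `features.tsv` (gene ids) sidecars.
#'
#' @param path file (dense_tsv) or directory (mtx_triplet).
#' @param format `"dense_tsv"` or `"mtx_triplet"`.
#' @return list with `expression` (dense spots-by-genes matrix),
#'   `spot_ids`, `gene_ids`.
#' @export
read_expression <- function(path, format = c("dense_tsv", "mtx_triplet")) {
  format <- match.arg(format)
  if (format == "dense_tsv") {
    tab <- utils::read.delim(path, check.names = FALSE, row.names = 1)
    mat <- as.matrix(tab)
    if (!is.numeric(mat)) stop("non-numeric cells in expression table: ", path)
    return(list(expression = mat, spot_ids = rownames(mat),
                gene_ids = colnames(mat)))
  }
  mtx <- file.path(path, "matrix.mtx")
  bcs <- file.path(path, "barcodes.tsv")
  fts <- file.path(path, "features.tsv")
  for (f in c(mtx, bcs, fts)) {
    if (!file.exists(f)) stop("missing input path: ", f)
  }
  M <- as.matrix(Matrix::readMM(mtx))
  storage.mode(M) <- "double"
  spot_ids <- readLines(bcs)
  gene_ids <- vapply(strsplit(readLines(fts), "\t"), `[[`, "", 1)
  if (nrow(M) != length(gene_ids) || ncol(M) != length(spot_ids)) {
    stop("matrix dimensions do not match sidecar files in ", path)
  }
  mat <- t(M)
  dimnames(mat) <- list(spot_ids, gene_ids)
  list(expression = mat, spot_ids = spot_ids, gene_ids = gene_ids)
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]; round-trips are value-exact.
#'
#' @param expression spots-by-genes matrix with dimnames.
#' @param path output file (dense_tsv) or directory (mtx_triplet).
#' @param format `"dense_tsv"` or `"mtx_triplet"`.
#' @export
write_expression <- function(expression, path,
                             format = c("dense_tsv", "mtx_triplet")) {
  format <- match.arg(format)
  if (format == "dense_tsv") {
    ## 17 significant digits round-trip IEEE doubles exactly
    chr <- apply(expression, 2, function(col) sprintf("%.17g", col))
    tab <- data.frame(spot_id = rownames(expression), chr,
                      check.names = FALSE)
    colnames(tab) <- c("spot_id", colnames(expression))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(t(expression), sparse = TRUE),
                  file.path(path, "matrix.mtx"))
  writeLines(rownames(expression), file.path(path, "barcodes.tsv"))
  writeLines(paste(colnames(expression), colnames(expression), sep = "\t"),
             file.path(path, "features.tsv"))
  invisible(path)
}

#' Read spot coordinates
#'
#' TSV with columns `spot_id`, `x`, `y`.
#'
#' @param path file path.
#' @return matrix of coordinates with spot ids as row names.
#' @export
read_coordinates <- function(path) {
  tab <- utils::read.delim(path)
  out <- as.matrix(tab[, c("x", "y")])
  rownames(out) <- tab$spot_id
  out
}

#' Read per-spot region labels
#'
#' TSV with columns `spot_id`, `region`.
#'
#' @param path file path.
#' @return named character vector of region labels.
#' @export
read_regions <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character")
  stats::setNames(tab$region, tab$spot_id)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then members. Member order is preserved; duplicate members are dropped
#' with a warning.
#'
#' @param path GMT file path.
#' @return named list of [gene_set()] objects.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("malformed GMT line %d: fewer than 3 fields", i))
    }
    gene_set(fields[1], fields[-(1:2)])
  })
  names(sets) <- vapply(sets, function(s) s$name, "")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets list of [gene_set()] objects.
#' @param path output path.
#' @param description description field (recycled).
#' @export
write_gene_sets <- function(sets, path, description = "") {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, description, s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Assemble a spatial dataset from files
#'
#' @param expression_path,format passed to [read_expression()].
#' @param coordinates_path TSV of spot coordinates (optional).
#' @param regions_path TSV of region labels.
#' @return a [spatial_dataset()] with spots ordered as in the expression
#'   input.
#' @export
read_spatial_dataset <- function(expression_path, regions_path,
                                 coordinates_path = NULL,
                                 format = "dense_tsv") {
  ex <- read_expression(expression_path, format)
  regions <- read_regions(regions_path)
  if (!all(ex$spot_ids %in% names(regions))) {
    stop("region file missing labels for some spots")
  }
  coords <- NULL
  if (!is.null(coordinates_path)) {
    cc <- read_coordinates(coordinates_path)
    coords <- cc[ex$spot_ids, , drop = FALSE]
  }
  spatial_dataset(ex$expression, coords, regions[ex$spot_ids],
                  spot_ids = ex$spot_ids, gene_ids = ex$gene_ids)
}

#' Write a test result table
#'
#' TSV with one row per scope (`scope`, `n_spots`, `statistic`, `p`,
#' `n_perm`, `q`), p and q formatted to 6 significant digits.
#'
#' @param result a `spotcorr_test`.
#' @param path output path.
#' @export
write_test_result <- function(result, path) {
  tab <- result$table
  tab$statistic <- signif(tab$statistic, 6)
  tab$p <- signif(tab$p, 6)
  tab$q <- signif(tab$q, 6)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
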
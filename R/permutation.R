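#' Sequential Monte Carlo permutation configuration
#'
#' Controls permutation inference. Draws from the permutation null stop as
#' soon as `t` null statistics reach the observed value (large p values
#' need few draws), and are capped at `g - 1` draws for small p values.
#'
#' @param t exceedance target (default 20).
#' @param g permutation cap; the smallest reportable p value is `1/g`
#'   (default 10000).
#' @param seed optional integer seed; when set, test drivers are
#'   bit-reproducible.
#' @param alpha significance level used for BH screening (default 0.05).
#' @return object of class `smc_config`.
#' @export
smc_config <- function(t = 20, g = 10000, seed = NULL, alpha = 0.05) {
  if (t < 1) stop("t must be >= 1")
  if (g <= t) stop("g must exceed t")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(t = as.integer(t), g = as.integer(g), seed = seed,
                 alpha = alpha),
            class = "smc_config")
}

#' Permute expression profiles within regions
#'
#' Implements the WR-test's exchangeability null: under no spatially
#' varying correlation within a region, full normalized expression profiles
#' may be swapped between that region's spots. Coordinates and labels stay
#' fixed; the per-region multiset of profiles is preserved.
#'
#' @param dataset a `spatial_dataset`.
#' @param regions labels to permute (default: all).
#' @return a permuted `spatial_dataset`.
#' @export
permute_within_regions <- function(dataset, regions = unique(dataset$region_labels)) {
  Y <- dataset$expression
  for (r in regions) {
    rows <- which(dataset$region_labels == r)
    if (length(rows) > 1L) {
      Y[rows, ] <- Y[sample(rows), ]
    }
  }
  out <- dataset
  out$expression <- Y
  out
}

#' Center regions and permute residual profiles across a scope
#'
#' Implements the BR-test's null scheme: each region's spots are zero-mean
#' centered (the region-mean expression vector is subtracted), and the
#' residual profiles are then shuffled across all scope spots regardless of
#' region, removing between-region mean structure before permutation.
#'
#' @param dataset a `spatial_dataset`.
#' @param scope region labels forming the scope (default: all).
#' @return a `spatial_dataset` of centered, permuted residuals restricted
#'   to the scope spots.
#' @export
center_and_permute_residuals <- function(dataset,
                                         scope = unique(dataset$region_labels)) {
  rows <- which(dataset$region_labels %in% scope)
  sub <- dataset[rows]
  R <- center_regions(sub$expression, sub$region_labels)
  sub$expression <- R[sample(nrow(R)), , drop = FALSE]
  rownames(sub$expression) <- sub$spot_ids
  sub
}

center_regions <- function(Y, labels) {
  for (r in unique(labels)) {
    rows <- which(labels == r)
    Y[rows, ] <- sweep(Y[rows, , drop = FALSE], 2,
                       colMeans(Y[rows, , drop = FALSE]))
  }
  Y
}

#' Sequential Monte Carlo permutation p value
#'
#' Draws null statistics one at a time until `t` of them reach the
#' observed value, returning `p = t / l` with `l` the number of draws; if
#' `g - 1` draws are reached first, returns `p = (u + 1) / g` with `u` the
#' exceedance count. Ties (null equal to observed) count as exceedances,
#' which is conservative.
#'
#' @param observed observed statistic.
#' @param sampler zero-argument function returning one fresh null
#'   statistic per call.
#' @param config an [smc_config()].
#' @return list with `p` and `n_perm` (draws consumed).
#' @export
smc_pvalue <- function(observed, sampler, config = smc_config()) {
  t_target <- config$t
  cap <- config$g - 1L
  u <- 0L
  l <- 0L
  while (l < cap) {
    l <- l + 1L
    if (sampler() >= observed) {
      u <- u + 1L
      if (u == t_target) {
        return(list(p = t_target / l, n_perm = l))
      }
    }
  }
  list(p = (u + 1) / config$g, n_perm = l)
}

#' Benjamini-Hochberg adjusted q values
#'
#' Standard step-up FDR adjustment (thin wrapper over
#' [stats::p.adjust()]).
#'
#' @param pvalues numeric p values in (0, 1].
#' @return q values of the same length.
#' @export
benjamini_hochberg <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

new_test_result <- function(test, table, excluded, geneset, kernel, smc) {
  structure(list(test = test, table = table, excluded_regions = excluded,
                 geneset = geneset, kernel_config = kernel,
                 smc_config = smc),
            class = "spotcorr_test")
}

#' @export
print.spotcorr_test <- function(x, ...) {
  cat(sprintf("%s-test for gene set '%s'\n", toupper(x$test), x$geneset))
  print(x$table, row.names = FALSE, digits = 4)
  if (length(x$excluded_regions)) {
    cat("excluded regions:", paste(x$excluded_regions, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.spotcorr_test <- function(object, ...) {
  tab <- object$table
  cat(sprintf("%s-test, gene set '%s': %d scope(s), %d significant at q < %g\n",
              toupper(object$test), object$geneset, nrow(tab),
              sum(tab$q < object$smc_config$alpha),
              object$smc_config$alpha))
  invisible(object)
}

#' Within-region test for spatially varying correlation
#'
#' For each tissue region that survives the effective-neighbors filter,
#' tests whether the gene set's correlation structure varies smoothly in
#' space within the region, using the MVN likelihood-ratio statistic
#' comparing spot-wise kernel correlations (alternative) against the
#' constant region-wide Pearson correlation (null). Significance comes
#' from sequential Monte Carlo permutation of expression profiles within
#' the region, with fresh kernel estimates per permutation; FDR is
#' controlled across regions by Benjamini-Hochberg.
#'
#' @param dataset a `spatial_dataset` of normalized expression.
#' @param geneset genes (ids or a [gene_set()]), at least 2.
#' @param kernel a [kernel_config()].
#' @param smc an [smc_config()].
#' @param provider a [distance_provider()].
#' @return a `spotcorr_test` object; `$table` has one row per tested
#'   region with columns `scope`, `n_spots`, `statistic`, `p`, `n_perm`,
#'   `q`.
#' @export
run_wr_test <- function(dataset, geneset, kernel = kernel_config(),
                        smc = smc_config(), provider = distance_provider()) {
  genes <- resolve_genes(dataset, geneset)
  if (length(genes) < 2L) stop("gene set must contain at least 2 genes")
  if (!is.null(smc$seed)) set.seed(smc$seed)
  prep <- prepare_dataset(dataset, kernel, provider)
  ds <- prep$dataset
  regions <- sort(unique(ds$region_labels))
  testable <- regions[vapply(regions, function(r)
    sum(ds$region_labels == r) >= 3L, TRUE)]
  if (!length(testable)) {
    stop("no testable regions remain after the effective-neighbors filter")
  }
  Wn_all <- normalize_weights(prep$weights)
  rows_list <- lapply(testable, function(r) which(ds$region_labels == r))
  res <- lapply(seq_along(testable), function(k) {
    rows <- rows_list[[k]]
    Y <- ds$expression[rows, genes, drop = FALSE]
    Wn <- Wn_all[rows, rows, drop = FALSE]
    R_null <- stats::cor(Y)
    obs <- wr_stat_fast(Y, Wn, R_null)
    sampler <- function() {
      wr_stat_fast(Y[sample(nrow(Y)), , drop = FALSE], Wn, R_null)
    }
    sm <- smc_pvalue(obs, sampler, smc)
    data.frame(scope = testable[k], n_spots = length(rows), statistic = obs,
               p = sm$p, n_perm = sm$n_perm, capped = sm$n_perm >= smc$g - 1L,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  tab$q <- benjamini_hochberg(tab$p)
  new_test_result("wr", tab, setdiff(unique(dataset$region_labels), testable),
                  geneset_name(geneset), kernel, smc)
}

#' Between-region test for differing correlation structure
#'
#' Tests whether the gene set's (internally constant) correlation structure
#' differs between tissue regions. Regions showing significant
#' within-region variation per a prior WR screen are excluded (the
#' between-region contrast is not well defined for them). In `pairwise`
#' mode every unordered pair of surviving regions is tested; in
#' `all-regions` mode a single statistic contrasts per-region correlations
#' against the slide-wide pooled correlation. Null draws center each
#' region's profiles and permute the residuals across the scope.
#'
#' @inheritParams run_wr_test
#' @param wr optional `spotcorr_test` from [run_wr_test()] on the same
#'   gene set, used to screen out regions with WR q below `smc$alpha`;
#'   `NULL` exempts all regions from the screen.
#' @param mode `"pairwise"` or `"all-regions"`.
#' @return a `spotcorr_test` object with one row per region pair (or one
#'   row for `all-regions`).
#' @export
run_br_test <- function(dataset, geneset, kernel = kernel_config(),
                        smc = smc_config(), wr = NULL,
                        mode = c("pairwise", "all-regions"),
                        provider = distance_provider()) {
  mode <- match.arg(mode)
  genes <- resolve_genes(dataset, geneset)
  if (length(genes) < 2L) stop("gene set must contain at least 2 genes")
  if (!is.null(smc$seed)) set.seed(smc$seed)
  prep <- prepare_dataset(dataset, kernel, provider)
  ds <- prep$dataset
  regions <- sort(unique(ds$region_labels))
  regions <- regions[vapply(regions, function(r)
    sum(ds$region_labels == r) >= 3L, TRUE)]
  screened <- character(0)
  if (!is.null(wr)) {
    if (!inherits(wr, "spotcorr_test") || wr$test != "wr") {
      stop("'wr' must be a WR-test result")
    }
    screened <- wr$table$scope[wr$table$q < smc$alpha]
    regions <- setdiff(regions, screened)
  }
  if (length(regions) < 2L) {
    stop("BR-test not testable: fewer than 2 regions survive filtering and the WR screen")
  }
  Wn_all <- normalize_weights(prep$weights)
  scopes <- if (mode == "pairwise") {
    utils::combn(regions, 2, simplify = FALSE)
  } else {
    list(regions)
  }
  res <- lapply(scopes, function(sc) {
    rows <- which(ds$region_labels %in% sc)
    Y <- ds$expression[rows, genes, drop = FALSE]
    labs <- ds$region_labels[rows]
    region_rows <- lapply(sc, function(r) which(labs == r))
    names(region_rows) <- sc
    Wn_list <- lapply(region_rows, function(rr)
      Wn_all[rows[rr], rows[rr], drop = FALSE])
    obs <- br_stat_fast(Y, region_rows, Wn_list)
    ## null draws: center per region once, then shuffle residual rows; the
    ## pooled correlation of the centered residuals is permutation-invariant
    Yc <- center_regions(Y, labs)
    R_pool_c <- stats::cor(Yc)
    sampler <- function() {
      br_stat_fast(Yc[sample(nrow(Yc)), , drop = FALSE], region_rows,
                   Wn_list, R_pool_c)
    }
    sm <- smc_pvalue(obs, sampler, smc)
    data.frame(scope = paste(sc, collapse = "|"), n_spots = length(rows),
               statistic = obs, p = sm$p, n_perm = sm$n_perm,
               capped = sm$n_perm >= smc$g - 1L, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  tab$q <- benjamini_hochberg(tab$p)
  out <- new_test_result("br", tab, screened, geneset_name(geneset),
                         kernel, smc)
  out$mode <- mode
  out
}

#' Rank gene pairs by their contribution to differential correlation
#'
#' Runs the designated test on every unordered pair of genes in a set and
#' ranks pairs by their smallest p value over scopes, ascending (ties
#' broken by gene-id order), so the pairs driving a set-level call can be
#' identified.
#'
#' @inheritParams run_wr_test
#' @param test `"wr"` or `"br"`.
#' @param wr optional WR screen result passed through to [run_br_test()].
#' @param mode BR scope mode, passed through to [run_br_test()].
#' @return data.frame with columns `gene_1`, `gene_2`, `p` (minimum over
#'   scopes), `scope` (where the minimum occurred), sorted ascending by p.
#' @export
rank_gene_pairs <- function(dataset, geneset, test = c("wr", "br"),
                            kernel = kernel_config(), smc = smc_config(),
                            wr = NULL, mode = "pairwise",
                            provider = distance_provider()) {
  test <- match.arg(test)
  genes <- resolve_genes(dataset, geneset)
  if (length(genes) < 2L) stop("gene set must contain at least 2 genes")
  pairs <- utils::combn(sort(genes), 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    fit <- if (test == "wr") {
      run_wr_test(dataset, pr, kernel, smc, provider)
    } else {
      run_br_test(dataset, pr, kernel, smc, wr = wr, mode = mode,
                  provider = provider)
    }
    k <- which.min(fit$table$p)
    data.frame(gene_1 = pr[1], gene_2 = pr[2], p = fit$table$p[k],
               scope = fit$table$scope[k], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p, out$gene_1, out$gene_2), , drop = FALSE]
}
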
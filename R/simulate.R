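#' Poisson-lognormal marginal parameters
#'
#' Per-region, per-gene latent means and variances of the log rate in the
#' Poisson-lognormal count model `y ~ Poisson(s * lambda)`,
#' `log lambda ~ N(mu, sigma2)` (plus gene-gene dependence supplied by a
#' latent correlation field).
#'
#' @param mu numeric matrix, regions in rows, genes in columns: latent
#'   means of `log lambda`.
#' @param sigma2 matrix of the same shape: latent variances (positive).
#' @return object of class `marginal_params`.
#' @export
marginal_params <- function(mu, sigma2) {
  mu <- as.matrix(mu)
  sigma2 <- as.matrix(sigma2)
  if (!all(dim(mu) == dim(sigma2))) stop("mu and sigma2 shapes differ")
  if (any(sigma2 <= 0)) stop("sigma2 must be positive")
  structure(list(mu = mu, sigma2 = sigma2), class = "marginal_params")
}

#' Radial basis function kernel matrix for the simulator
#'
#' The Gaussian-process prior over latent correlation fields uses the RBF
#' kernel `exp(-||s_i - s_j||^2 / bandwidth)` — squared distance, unlike
#' the testing kernel, which decays in plain distance.
#'
#' @param coordinates N-by-d coordinate matrix.
#' @param bandwidth positive squared-distance decay scale.
#' @return symmetric PSD N-by-N matrix with unit diagonal.
#' @export
rbf_kernel_matrix <- function(coordinates, bandwidth) {
  if (bandwidth <= 0) stop("bandwidth must be positive")
  D <- as.matrix(stats::dist(coordinates))
  exp(-D^2 / bandwidth)
}

## Draw one N-vector from MVN(0, c * K) via Cholesky (small ridge for
## numerical PSD); c = 0 short-circuits to zeros.
gp_draw <- function(K, c, n_draws = 1) {
  N <- nrow(K)
  if (c == 0) return(matrix(0, N, n_draws))
  L <- chol(K + diag(1e-8, N))
  sqrt(c) * t(L) %*% matrix(stats::rnorm(N * n_draws), N, n_draws)
}

#' Sample a smooth latent correlation field for a gene pair
#'
#' Fisher-transformed correlations are drawn from a zero-mean Gaussian
#' process with covariance `c * K` and mapped back through `tanh`, giving
#' per-spot correlations strictly inside (-1, 1) that vary smoothly over
#' the slide. The covariance strength `c` scales how far correlations
#' stray from zero.
#'
#' @param K PSD kernel matrix from [rbf_kernel_matrix()].
#' @param c nonnegative covariance strength.
#' @param sd1,sd2 optional latent standard deviations of the two genes;
#'   when given, the per-spot latent covariance `r_i * sd1 * sd2` is
#'   included in the result.
#' @return object of class `latent_field`, mode `"pair"`, with per-spot
#'   `r` (and `sigma12` when sds are supplied).
#' @export
sample_pair_correlation_field <- function(K, c, sd1 = NULL, sd2 = NULL) {
  if (c < 0) stop("c must be >= 0")
  z <- drop(gp_draw(K, c))
  r <- tanh(z)
  out <- list(mode = "pair", r = r, fisher = z)
  if (!is.null(sd1) && !is.null(sd2)) out$sigma12 <- r * sd1 * sd2
  structure(out, class = "latent_field")
}

#' Constant (region-wise) correlation field for a gene pair or set
#'
#' Builds a latent field with a fixed correlation per spot — used for
#' between-region scenarios where correlation is constant within each
#' region but differs between region groups. With more than two genes the
#' correlation is applied to every gene pair (compound symmetry), which
#' requires nonnegative correlations.
#'
#' @param r per-spot correlation vector.
#' @param n_genes number of genes the field applies to.
#' @return a `latent_field` of mode `"pair"` (2 genes) or `"cs"`.
#' @export
constant_correlation_field <- function(r, n_genes = 2) {
  if (n_genes > 2 && any(r < 0)) {
    stop("compound-symmetry fields require nonnegative correlations")
  }
  if (any(abs(r) >= 1)) stop("correlations must lie strictly inside (-1, 1)")
  structure(list(mode = if (n_genes == 2) "pair" else "cs",
                 r = r, n_genes = n_genes),
            class = "latent_field")
}

#' Sample a smooth latent covariance field for a gene set
#'
#' For each gene, an N-vector `v_g` is drawn from a Gaussian process with
#' covariance `c * K`; stacking the spot-level values `z_i = (v_{1,i}, ...,
#' v_{G,i})` gives the per-spot latent covariance `Phi + z_i z_i'` — a
#' rank-1 update of a positive diagonal, hence positive semidefinite by
#' construction, whose entries vary smoothly across the slide.
#'
#' @param K PSD kernel matrix.
#' @param c nonnegative covariance strength.
#' @param phi positive per-gene latent variances (diagonal of Phi).
#' @param n_genes number of genes G.
#' @return a `latent_field` of mode `"multigene"` with `Z` (N-by-G) and
#'   `phi`.
#' @export
sample_multigene_covariance_field <- function(K, c, phi, n_genes = length(phi)) {
  if (c < 0) stop("c must be >= 0")
  if (length(phi) == 1L) phi <- rep(phi, n_genes)
  if (any(phi <= 0)) stop("phi must be positive")
  Z <- gp_draw(K, c, n_draws = n_genes)
  structure(list(mode = "multigene", Z = Z, phi = phi, n_genes = n_genes),
            class = "latent_field")
}

#' Per-spot latent covariance matrices of a field
#'
#' @param field a `latent_field`.
#' @param marginals a `marginal_params` (needed for pair/cs modes to scale
#'   correlations by the latent sds; the first region's variances are
#'   used).
#' @return array (N, G, G) of latent covariance matrices.
#' @export
field_covariances <- function(field, marginals = NULL) {
  if (field$mode == "multigene") {
    N <- nrow(field$Z)
    G <- field$n_genes
    out <- array(0, dim = c(N, G, G))
    for (g in seq_len(G)) for (h in seq_len(G)) {
      out[, g, h] <- field$Z[, g] * field$Z[, h] + (g == h) * field$phi[g]
    }
    return(out)
  }
  if (is.null(marginals)) stop("pair/cs fields need marginal_params")
  s2 <- marginals$sigma2[1, ]
  G <- if (field$mode == "pair") 2L else field$n_genes
  N <- length(field$r)
  out <- array(0, dim = c(N, G, G))
  for (g in seq_len(G)) for (h in seq_len(G)) {
    out[, g, h] <- if (g == h) s2[g] else field$r * sqrt(s2[g] * s2[h])
  }
  out
}

#' Latent gene-gene correlation at each spot
#'
#' Ground-truth per-spot correlation implied by a latent field for a
#' designated gene pair.
#'
#' @param field a `latent_field`.
#' @param pair indices of the two genes (multigene mode).
#' @return numeric vector of per-spot correlations.
#' @export
field_correlation <- function(field, pair = c(1, 2)) {
  if (field$mode %in% c("pair", "cs")) return(field$r)
  zg <- field$Z[, pair[1]]
  zh <- field$Z[, pair[2]]
  zg * zh / sqrt((field$phi[pair[1]] + zg^2) * (field$phi[pair[2]] + zh^2))
}

#' Simulate UMI counts from the Poisson-lognormal model
#'
#' Draws per-spot latent log rates from the multivariate normal implied by
#' the marginal parameters and the latent correlation field, then counts
#' from `Poisson(s_i * lambda)`. Spots are mutually independent; all
#' dependence is between genes within a spot. Region parameters are
#' applied independently per region.
#'
#' @param marginals a [marginal_params()] whose rows are named by region.
#' @param field a `latent_field`.
#' @param region_labels per-spot region labels matching the marginals'
#'   row names.
#' @param size_factors positive per-spot exposures.
#' @return integer count matrix, spots by genes.
#' @export
simulate_counts <- function(marginals, field, region_labels, size_factors) {
  N <- length(region_labels)
  if (any(size_factors <= 0)) stop("size factors must be positive")
  ridx <- match(region_labels, rownames(marginals$mu))
  if (anyNA(ridx)) stop("region labels missing from marginal parameters")
  if (field$mode == "pair") {
    mu <- marginals$mu[ridx, , drop = FALSE]
    sd <- sqrt(marginals$sigma2[ridx, , drop = FALSE])
    r <- field$r
    e1 <- stats::rnorm(N)
    e2 <- stats::rnorm(N)
    log_lam <- cbind(mu[, 1] + sd[, 1] * e1,
                     mu[, 2] + sd[, 2] * (r * e1 + sqrt(1 - r^2) * e2))
  } else if (field$mode == "cs") {
    G <- field$n_genes
    mu <- marginals$mu[ridx, , drop = FALSE]
    sd <- sqrt(marginals$sigma2[ridx, , drop = FALSE])
    eps <- matrix(stats::rnorm(N * G), N, G)
    eta <- stats::rnorm(N)
    r <- field$r
    log_lam <- mu + sd * (sqrt(1 - r) * eps + sqrt(r) * eta)
  } else {
    G <- field$n_genes
    mu <- marginals$mu[ridx, , drop = FALSE]
    eps <- matrix(stats::rnorm(N * G), N, G)
    eta <- stats::rnorm(N)
    log_lam <- mu + sweep(eps, 2, sqrt(field$phi), "*") + field$Z * eta
  }
  lam <- exp(log_lam)
  counts <- matrix(stats::rpois(length(lam), size_factors * lam),
                   nrow = N)
  storage.mode(counts) <- "integer"
  counts
}

## Expression-level presets: target mean UMI counts per spot for the four
## levels used throughout the simulation scenarios, spanning lowly to
## highly expressed genes on a typical Visium slide.
expression_level_targets <- c(low = 2, modlow = 5, modhigh = 10, high = 20)

default_marginals <- function(regions, n_genes, level = "modhigh",
                              sigma2 = 0.3, median_library = 10000,
                              target = NULL) {
  if (is.null(target)) target <- expression_level_targets[[level]]
  mu_val <- log(target / median_library) - sigma2 / 2
  mu <- matrix(mu_val, length(regions), n_genes,
               dimnames = list(regions, paste0("gene_", seq_len(n_genes))))
  s2 <- matrix(sigma2, length(regions), n_genes, dimnames = dimnames(mu))
  marginal_params(mu, s2)
}

lattice_layout <- function(n_row, n_col, bands = 1) {
  coords <- cbind(x = rep(seq_len(n_col), each = n_row),
                  y = rep(seq_len(n_row), times = n_col))
  band <- ceiling(coords[, "x"] / (n_col / bands))
  list(coordinates = coords, region_labels = paste0("R", band))
}

#' Generate a simulation scenario
#'
#' Produces a complete synthetic dataset on a rectangular spot lattice
#' under one of six preset scenarios, with ground truth:
#' \describe{
#'   \item{SimI}{gene pair, five vertical-band regions, smoothly varying
#'     correlation (GP field) at covariance strength `c`.}
#'   \item{SimII}{multi-gene set, five regions, smooth covariance field
#'     (`Phi + z z'` construction) at `c`.}
#'   \item{SimIII}{gene pair, five regions in two groups; correlation
#'     constant within regions, 0 in one group and `diff` in the other.}
#'   \item{SimIV}{multi-gene version of SimIII: pairwise correlations 0
#'     vs `diff` between the groups.}
#'   \item{SimV}{gene pair, two half-slide regions, no correlation
#'     anywhere, but mean expression differs between the regions.}
#'   \item{SimVI}{gene pair, single whole-slide region, smooth GP
#'     correlation at `c`.}
#' }
#'
#' @param name scenario name, `"SimI"` ... `"SimVI"`.
#' @param expression_level `"low"`, `"modlow"`, `"modhigh"` or `"high"`
#'   (target mean UMI counts 2, 5, 10, 20).
#' @param c covariance strength for GP scenarios (SimI default 0.1, SimII
#'   0.1, SimVI 0.05).
#' @param diff between-group correlation difference (SimIII/SimIV,
#'   default 0.2).
#' @param n_genes gene-set size for SimII/SimIV (default 9).
#' @param n_row,n_col lattice dimensions (default 25 x 40 = 1000 spots).
#' @param gamma_sim RBF bandwidth of the GP (squared-distance scale,
#'   default 25).
#' @param sigma2 latent log-rate variance (default 0.3).
#' @param seed optional integer seed.
#' @return object of class `sim_scenario`: list with `dataset` (a
#'   `spatial_dataset` of raw counts with size factors), `field` (the
#'   `latent_field`), `truth` (list with `null` flag and per-spot latent
#'   correlation `r`), and `name`.
#' @export
generate_scenario <- function(name = c("SimI", "SimII", "SimIII", "SimIV",
                                       "SimV", "SimVI"),
                              expression_level = "modhigh", c = NULL,
                              diff = 0.2, n_genes = 9, n_row = 25,
                              n_col = 40, gamma_sim = 25, sigma2 = 0.3,
                              seed = NULL) {
  name <- match.arg(name)
  if (!is.null(seed)) set.seed(seed)
  bands <- switch(name, SimV = 2L, SimVI = 1L, 5L)
  lay <- lattice_layout(n_row, n_col, bands)
  N <- nrow(lay$coordinates)
  regions <- sort(unique(lay$region_labels))
  size_factors <- stats::rlnorm(N, log(10000), 0.3)
  G <- switch(name, SimII = n_genes, SimIV = n_genes, 2L)
  marg <- default_marginals(regions, G, expression_level, sigma2)
  if (name == "SimV") {
    ## differing means between the two halves: one region one expression
    ## level up (4x the target mean), correlation zero everywhere
    marg$mu["R2", ] <- marg$mu["R2", ] + log(4)
  }
  field <- switch(name,
    SimI = {
      if (is.null(c)) c <- 0.1
      K <- rbf_kernel_matrix(lay$coordinates, gamma_sim)
      sample_pair_correlation_field(K, c)
    },
    SimII = {
      if (is.null(c)) c <- 0.1
      K <- rbf_kernel_matrix(lay$coordinates, gamma_sim)
      sample_multigene_covariance_field(K, c, phi = rep(sigma2, G))
    },
    SimIII = {
      grp_b <- lay$region_labels %in% c("R3", "R4", "R5")
      constant_correlation_field(ifelse(grp_b, diff, 0), 2)
    },
    SimIV = {
      grp_b <- lay$region_labels %in% c("R3", "R4", "R5")
      constant_correlation_field(ifelse(grp_b, diff, 0), G)
    },
    SimV = constant_correlation_field(rep(0, N), 2),
    SimVI = {
      if (is.null(c)) c <- 0.05
      K <- rbf_kernel_matrix(lay$coordinates, gamma_sim)
      sample_pair_correlation_field(K, c)
    }
  )
  counts <- simulate_counts(marg, field, lay$region_labels, size_factors)
  colnames(counts) <- colnames(marg$mu)
  ds <- spatial_dataset(counts, lay$coordinates, lay$region_labels,
                        size_factors = size_factors)
  null_truth <- switch(name,
    SimI = !is.null(c) && c == 0,
    SimII = c == 0,
    SimIII = diff == 0,
    SimIV = diff == 0,
    SimV = TRUE,
    SimVI = c == 0
  )
  structure(list(name = name, dataset = ds, field = field,
                 marginals = marg,
                 truth = list(null = null_truth,
                              r = field_correlation(field))),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("%s scenario: %d spots, %d genes, %s\n", x$name,
              nrow(x$dataset$expression), ncol(x$dataset$expression),
              if (x$truth$null) "null" else "alternative"))
  invisible(x)
}

#' Log-CPM fallback normalization
#'
#' Scales counts by the per-spot library size (the dataset's size factors,
#' or the row sums when absent) to counts per `scale` and applies
#' `log1p`. This is a generic library-size normalization, intended as a
#' fallback when no model-based normalization of the counts is available.
#'
#' @param dataset a `spatial_dataset` of counts.
#' @param scale counts-per-`scale` target (default 1e4).
#' @return a `spatial_dataset` with normalized expression.
#' @export
normalize_logcpm <- function(dataset, scale = 1e4) {
  s <- dataset$size_factors
  if (is.null(s)) s <- rowSums(dataset$expression)
  if (any(s <= 0)) stop("nonpositive library size; cannot normalize")
  out <- dataset
  out$expression <- log1p(dataset$expression / s * scale)
  out
}

#' Estimate Poisson-lognormal marginal parameters from counts
#'
#' Per region and gene, returns posterior means of the latent log-rate
#' mean and variance under the Poisson-lognormal likelihood with a normal
#' prior on the mean (centered at the gene's naive log rate) and a
#' truncated half-Cauchy prior on the latent standard deviation. The
#' posterior is integrated numerically on a (mu, sigma) grid with
#' Gauss-Hermite quadrature over the latent log rate, so estimates are
#' deterministic.
#'
#' @param counts nonnegative integer matrix, spots by genes.
#' @param size_factors positive per-spot exposures.
#' @param region_labels per-spot region labels.
#' @param prior list with `mu_sd` (normal prior sd, default 2),
#'   `cauchy_scale` (default 1) and `sigma_max` (truncation, default 5).
#' @param grid list with `n_mu`, `n_sigma`, `n_quad` controlling the
#'   numerical integration. The posterior is evaluated on a coarse grid
#'   first and then on a refined grid around the posterior mode, so sharp
#'   posteriors (large regions) are integrated accurately.
#' @return a `marginal_params` with an extra `flagged` logical matrix
#'   marking genes that were all zero within a region (prior-fallback
#'   estimates, reported with a warning).
#' @export
estimate_marginals <- function(counts, size_factors, region_labels,
                               prior = list(mu_sd = 2, cauchy_scale = 1,
                                            sigma_max = 5),
                               grid = list(n_mu = 25, n_sigma = 25,
                                           n_quad = 20)) {
  counts <- as.matrix(counts)
  regions <- sort(unique(region_labels))
  G <- ncol(counts)
  gh <- pracma::gaussHermite(grid$n_quad)
  log_w <- log(gh$w) - 0.5 * log(pi)
  mu_hat <- matrix(NA_real_, length(regions), G,
                   dimnames = list(regions, colnames(counts)))
  s2_hat <- mu_hat
  flagged <- matrix(FALSE, length(regions), G, dimnames = dimnames(mu_hat))

  post_on_grid <- function(y, log_s, center, mu_grid, sig_grid) {
    ll <- matrix(0, length(mu_grid), length(sig_grid))
    for (sj in seq_along(sig_grid)) {
      tk <- sqrt(2) * sig_grid[sj] * gh$x  # latent offsets about mu
      for (mi in seq_along(mu_grid)) {
        lp <- stats::dpois(y, exp(outer(log_s, mu_grid[mi] + tk, "+")),
                           log = TRUE) +
          rep(log_w, each = length(y))
        mx <- apply(lp, 1, max)
        ll[mi, sj] <- sum(mx + log(rowSums(exp(lp - mx))))
      }
    }
    post <- ll + outer(stats::dnorm(mu_grid, center, prior$mu_sd, log = TRUE),
                       stats::dcauchy(sig_grid, 0, prior$cauchy_scale,
                                      log = TRUE), "+")
    post <- exp(post - max(post))
    post / sum(post)
  }

  for (ri in seq_along(regions)) {
    rows <- which(region_labels == regions[ri])
    s <- size_factors[rows]
    log_s <- log(s)
    for (g in seq_len(G)) {
      y <- counts[rows, g]
      if (sum(y) == 0) {
        ## no information beyond the prior: floor estimate from the prior
        mu_hat[ri, g] <- log(0.5 / sum(s))
        s2_hat[ri, g] <- 1
        flagged[ri, g] <- TRUE
        warning(sprintf(
          "gene %s all zero in region %s; prior-fallback marginal estimate",
          colnames(counts)[g], regions[ri]))
        next
      }
      center <- log(sum(y) / sum(s))
      ## pass 1: coarse grid to locate the posterior mode
      mu1 <- seq(center - 2.5, center + 2.5, length.out = grid$n_mu)
      sig1 <- seq(0.02, prior$sigma_max, length.out = grid$n_sigma)
      p1 <- post_on_grid(y, log_s, center, mu1, sig1)
      peak <- which(p1 == max(p1), arr.ind = TRUE)[1, ]
      mu0 <- mu1[peak[1]]
      sg0 <- sig1[peak[2]]
      ## pass 2: refined grid around the mode (covers the posterior bulk
      ## even for large regions where the posterior is very sharp)
      dmu <- max(0.35, 1.5 * diff(mu1[1:2]))
      dsg <- max(0.2, 1.5 * diff(sig1[1:2]))
      mu2 <- seq(mu0 - dmu, mu0 + dmu, length.out = grid$n_mu)
      sig2 <- seq(max(0.005, sg0 - dsg), min(prior$sigma_max, sg0 + dsg),
                  length.out = grid$n_sigma)
      p2 <- post_on_grid(y, log_s, center, mu2, sig2)
      ## pass 3: zoom onto the posterior bulk so grid discretization is
      ## negligible relative to the posterior spread
      peak2 <- which(p2 == max(p2), arr.ind = TRUE)[1, ]
      mu_sd <- sqrt(max(sum(p2 * mu2^2) - sum(p2 * mu2)^2, 0))
      sg_mean <- sum(t(p2) * sig2)
      sg_sd <- sqrt(max(sum(t(p2) * sig2^2) - sg_mean^2, 0))
      dmu3 <- max(6 * mu_sd, 3 * diff(mu2[1:2]))
      dsg3 <- max(6 * sg_sd, 3 * diff(sig2[1:2]))
      mu3 <- seq(mu2[peak2[1]] - dmu3, mu2[peak2[1]] + dmu3,
                 length.out = grid$n_mu)
      sig3 <- seq(max(0.005, sig2[peak2[2]] - dsg3),
                  min(prior$sigma_max, sig2[peak2[2]] + dsg3),
                  length.out = grid$n_sigma)
      p3 <- post_on_grid(y, log_s, center, mu3, sig3)
      mu_hat[ri, g] <- sum(p3 * mu3)
      s2_hat[ri, g] <- sum(t(p3) * sig3^2)
    }
  }
  out <- marginal_params(mu_hat, s2_hat)
  out$flagged <- flagged
  out
}

#' Compare simulated and reference correlation variability
#'
#' For each simulated dataset and each reference gene pair, computes the
#' variance over spots of the kernel correlation estimates — the
#' diagnostic used to check that a chosen covariance strength produces
#' correlation patterns whose variability matches those seen in a
#' reference dataset.
#'
#' @param simulated list of normalized `spatial_dataset`s (each with at
#'   least 2 genes; the first two are used).
#' @param reference a normalized `spatial_dataset`, or `NULL` to skip.
#' @param pairs list of 2-gene character vectors to evaluate in the
#'   reference.
#' @param kernel a [kernel_config()].
#' @return data.frame with columns `source` (`"simulated"`/`"reference"`),
#'   `id`, `variance`.
#' @export
correlation_level_diagnostic <- function(simulated, reference = NULL,
                                         pairs = NULL,
                                         kernel = kernel_config()) {
  sim_rows <- lapply(seq_along(simulated), function(i) {
    ds <- simulated[[i]]
    fld <- correlation_field(ds, ds$gene_ids[1:2], kernel)
    data.frame(source = "simulated", id = as.character(i),
               variance = stats::var(fld$values), stringsAsFactors = FALSE)
  })
  ref_rows <- list()
  if (!is.null(reference) && length(pairs)) {
    ref_rows <- lapply(pairs, function(pr) {
      fld <- correlation_field(reference, pr, kernel)
      data.frame(source = "reference", id = paste(pr, collapse = "~"),
                 variance = stats::var(fld$values), stringsAsFactors = FALSE)
    })
  }
  do.call(rbind, base::c(sim_rows, ref_rows))
}
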
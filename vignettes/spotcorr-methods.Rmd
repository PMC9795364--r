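---
title: "Testing for spatially varying gene-gene correlation with spotcorr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing for spatially varying gene-gene correlation with spotcorr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotcorr)
```

## The problem

Spatial transcriptomics (ST) assays measure transcript counts at spatial
capture locations ("spots") across a tissue slide. Most analyses ask where
individual genes change in *mean* expression. `spotcorr` asks a different
question: where does the *co-expression structure* of a set of genes
change? Shifts in gene-gene correlation across a tissue — for example,
keratin pairs that are tightly coupled inside a tumor region but decoupled
outside it — indicate changes in coordinated regulation that mean-level
analyses cannot see.

Two hypothesis tests are provided, both operating on a normalized
spot-by-gene expression matrix $Y$ ($n$ spots, $m$ genes), 2-D spot
coordinates (or any precomputed spot-spot distance), and a per-spot tissue
region label:

* the **WR-test** (within-region) asks, for each region, whether the
  correlation structure of the gene set varies smoothly in space *inside*
  the region;
* the **BR-test** (between-region) asks whether an internally constant
  correlation structure *differs between* regions.

## The model and the statistic

Both tests compare two multivariate-normal models of the expression
profiles,

$$p_{\mathrm{alt}}(Y) = \prod_{i=1}^n \mathrm{MVN}(y_i;\, \mu_i,\,
S_i R_i^{(\mathrm{alt})} S_i), \qquad
p_{\mathrm{null}}(Y) = \prod_{i=1}^n \mathrm{MVN}(y_i;\, \mu_i,\,
S_i R_i^{(\mathrm{null})} S_i),$$

where $\mu_i$ is the spot-level mean vector, $S_i$ the diagonal matrix of
spot-level standard deviations, and $R_i$ a correlation matrix. The test
statistic is the log likelihood ratio
$T(Y) = \log p_{\mathrm{alt}}(Y) - \log p_{\mathrm{null}}(Y)$.

Crucially, $\mu_i$ and $S_i$ are *shared* between the two models, so the
ratio isolates correlation: spatial changes in mean or in variance cancel
and cannot drive the statistic. This is what lets the WR-test remain
calibrated on tissue where mean expression differs sharply between regions
(the half-slide scenario SimV below exercises exactly this failure mode of
naive spatial correlation tests).

Spot-level moments are estimated by region-masked kernel smoothing.
With kernel $K$ and bandwidth $\gamma$,

$$\mu_i = \frac{\sum_j 1[c_i = c_j]\, K(s_i, s_j; \gamma)\, y_j}
{\sum_j 1[c_i = c_j]\, K(s_i, s_j; \gamma)},$$

and the spot-level variances and covariances are the analogous weighted
averages of squared residuals and residual cross-products, with each
contributing spot's residual taken about *its own* kernel mean $\mu_j$
(the formula is implemented literally; using the focal spot's mean
instead changes the estimator). The indicator $1[c_i = c_j]$ masks the
kernel by region, so estimates in one region are provably unaffected by
expression anywhere else — the masking property the WR-test's
per-region inference relies on.

* **WR-test models** (per region): the alternative covariance is the full
  kernel covariance at each spot; the null covariance keeps the kernel
  variances on the diagonal but fills the off-diagonals from the single
  region-wide Pearson correlation $R_C$ scaled by the kernel standard
  deviations.
* **BR-test models** (per region pair, or all regions): the alternative
  gives every spot its *own region's* Pearson correlation; the null gives
  every spot the correlation pooled over the scope. Diagonals are kernel
  variances in both.

### Kernels, bandwidth, and spot filtering

Three kernel families are available: gaussian $\exp(-D/\gamma)$
(the default; note the *unsquared* distance), triangular
$\max(1 - D/\gamma, 0)$, and uniform $1[D < \gamma]$. The default
bandwidth $\gamma = 5$ is calibrated to 10x Visium array row/column
coordinates; coordinates are used in their native units and never
rescaled, so users of other platforms should set the bandwidth on their
own coordinate scale. Distances are Euclidean by default, but any
precomputed symmetric nonnegative matrix is accepted (e.g. shortest-path
distances along a cell-cell nearest-neighbor graph for dissociated data
ordered by pseudotime), and the triangle inequality is not assumed.

A spot's **effective neighbors** $\sum_j 1[c_i = c_j] K(s_i, s_j)$ is the
effective sample size behind its estimates; spots below the threshold
(default 10) are removed and weights are recomputed once on the surviving
spots. Filtering is single-pass: iterating it to a fixed point changes
little in practice and makes the analyzed spot set harder to reason
about.

### Significance

Permutation gives finite-sample validity without relying on the MVN model
being literally true. The WR null — no spatially varying correlation
within a region — makes that region's expression profiles exchangeable,
so null draws shuffle whole profiles among the region's spots. The BR
null scheme first zero-mean centers each region's profiles, then permutes
the residual profiles across the whole scope; centering removes the
between-region mean structure that is not under test. All kernel moments
are recomputed from scratch on every permuted dataset; the region
Pearson correlation (WR) and the pooled correlation of centered residuals
(BR) are mathematically invariant under their respective permutation
schemes and are computed once.

P values use sequential Monte Carlo stopping: draws continue until $t$
null statistics reach the observed one, giving $p = t/l$ after $l$ draws,
with a cap of $g - 1$ draws after which $p = (u + 1)/g$. Defaults
$t = 20$, $g = 10{,}000$. Ties between a null draw and the observed
statistic count as exceedances, which is the conservative direction.
Benjamini-Hochberg FDR control is applied across regions (WR) or region
pairs (BR). Regions whose WR q value falls below `alpha` are excluded
from all BR scopes, because a between-region contrast of "the" region
correlation is undefined for a region whose correlation is internally
varying; the cutoff is the same `alpha` as the screening level and is
exposed in `smc_config()`. Asymptotic $\chi^2$ p values are deliberately
out of scope.

### Numerical choices

A diagonal jitter of $10^{-10}$ is added symmetrically to the null and
alternative correlation matrices before factorization, so that model
equality still yields $T = 0$ exactly while near-duplicate genes do not
abort a permutation run; a covariance that remains singular after jitter
raises an error rather than silently pseudo-inverting. Genes with zero
variance within a scope raise a degenerate-gene error — silently dropping
a gene would silently change the hypothesis being tested. Per-spot
correlation estimates are clipped to $[-1, 1]$ only in the reporting
functions (`correlation_field()`), never inside the statistic.

## Uncertainty and pattern summaries

`bootstrap_correlation_ci()` puts a percentile interval around the
spot-level correlation estimate: spots within a fixed radius of the focal
spot *and in its region* are resampled with replacement, and the kernel
estimate at the focal spot is recomputed per resample using
focal-centered kernel weights with a single weighted mean per resample
(a per-spot kernel mean is not well defined on a resampled multiset).
The radius default is twice the kernel bandwidth — the paper-style
"fixed radius" with a concrete default; kernel weights are recomputed on
each resample rather than frozen.

`cluster_pair_patterns()` groups gene pairs whose per-spot correlation
fields follow similar spatial patterns, by average-linkage hierarchical
clustering of the per-pair correlation vectors under Euclidean distance.
Linkage and distance are genuinely open choices; these defaults are
standard, deterministic, and exposed as arguments.

## The simulator

The simulator draws UMI counts from a Poisson-lognormal model on a spot
lattice: $y_{i,g} \sim \mathrm{Poisson}(s_i \lambda_{i,g})$ with
$\log \lambda_i \sim \mathrm{MVN}(\mu, \Sigma_i)$, where $s_i$ is the
per-spot library size. Gene-gene dependence enters only through
$\Sigma_i$; spots are independent. Three latent-field constructions set
the per-spot correlation:

* **pair fields**: Fisher-transformed correlations are drawn from a
  Gaussian process, $\mathrm{atanh}(r) \sim \mathrm{MVN}(0, cK)$ with RBF
  kernel $K_{ij} = \exp(-\lVert s_i - s_j\rVert^2/\gamma_{\mathrm{sim}})$
  (squared distance — deliberately different from the testing kernel),
  and mapped back by $\tanh$; the latent covariance is
  $r_i \sigma_1 \sigma_2$.
* **multigene fields**: per gene, $v_g \sim \mathrm{MVN}(0, cK)$; per
  spot, $\Sigma_i = \Phi + z_i z_i^\top$ with
  $z_i = (v_{1,i}, \dots, v_{G,i})$ — a rank-1 update of a positive
  diagonal, PSD by construction, varying smoothly elementwise. The
  zero-mean construction is shifted by the per-region latent means
  $\mu_g$ when counts are drawn; without that shift the counts could not
  match per-region marginals.
* **constant fields**: a fixed correlation per spot (compound symmetry
  for more than two genes), for between-region scenarios.

The covariance strength $c$ controls how far correlations stray from
zero. Marginal parameters can be estimated from real counts with
`estimate_marginals()`: per region and gene, posterior means under the
Poisson-lognormal likelihood with a normal prior on $\mu$ (centered at
the naive log rate, scale 2) and a half-Cauchy prior on $\sigma$ (scale
1, truncated to $(0, 5]$), integrated on a coarse-then-refined
$(\mu, \sigma)$ grid with Gauss-Hermite quadrature — deterministic, no
MCMC. The prior hyperparameters are weakly informative defaults and are
configurable.

### Scenario presets and their defaults

`generate_scenario()` provides six presets on a 25 x 40 lattice (1000
spots; integer coordinates, matching the Visium-style bandwidth default):
five vertical-band regions (SimI-SimIV), a half-slide split with a
four-fold mean difference between halves (SimV), or a single whole-slide
region (SimVI). Ground truth (the per-spot latent correlation and a
null/alternative label) accompanies every dataset.

Defaults that the model description leaves open were fixed once, before
any testing, at values a practitioner would call realistic for Visium
data, and are not data-calibrated:

* four expression levels with target mean UMI counts 2 / 5 / 10 / 20 per
  spot, standing in for genes ranked from lowly to highly expressed;
* latent log-rate variance $\sigma_g^2 = 0.3$, and $\Phi$ equal to those
  per-gene variances in the multigene construction;
* library sizes lognormal with median 10,000 and log-sd 0.3;
* GP bandwidth $\gamma_{\mathrm{sim}} = 25$ on the squared-distance
  scale, i.e. a length scale of 5 lattice units, commensurate with the
  testing kernel's default reach;
* covariance strengths follow the preset grids
  (SimI: $c \in \{0, 0.05, 0.1, 0.2, 0.4\}$; SimII: $c = 0.1$;
  SimIII between-group differences $\{0, 0.2, 0.4, 0.8\}$ with one group
  at zero correlation; SimIV: 0 vs 0.2; SimVI:
  $c \in \{0.025, 0.05, 0.1\}$).

What the simulator emulates: overdispersed UMI counts with realistic
library-size variation, smooth latent correlation fields, region
structure, and mean differences between regions (SimV). What it does not:
spatial autocorrelation of library size, cell-type mixtures within spots,
zero inflation beyond Poisson-lognormal, platform artifacts, or
segmentation errors in region labels. Passing tests on these simulations
therefore demonstrate calibration and power under the model's own
assumptions, not robustness to everything real tissue can do; the
permutation construction is what protects calibration when the MVN model
is wrong.

## A worked example

```{r example, eval = FALSE}
scen <- generate_scenario("SimI", c = 0.4, seed = 1)
ds <- normalize_logcpm(scen$dataset)
wr <- run_wr_test(ds, ds$gene_ids, smc = smc_config(g = 1000, seed = 2))
wr
br_scen <- generate_scenario("SimIII", diff = 0.8,
                             expression_level = "high", seed = 3)
br_ds <- normalize_logcpm(br_scen$dataset)
wr_screen <- run_wr_test(br_ds, br_ds$gene_ids,
                         smc = smc_config(g = 1000, seed = 4))
br <- run_br_test(br_ds, br_ds$gene_ids,
                  smc = smc_config(g = 1000, seed = 5), wr = wr_screen)
br
```

## Validation study sizes

The package's statistical validation (in `tests/testthat/` and
`scripts/acceptance.R`) re-derives the headline operating characteristics
at desk scale, chosen as the package's own study sizes: false-positive
rates over 200 null datasets (50 per expression level) on the 1000-spot
lattice with the SMC cap at $g = 1000$ (the test suite runs a 50-replicate
smoke version at 500 spots), and power over 30 replicates per condition
with $g = 500$ — a p-value resolution of 1/500, far finer than the 0.05
call threshold these studies count. Normalization in all validation runs
is the log-CPM fallback computed from the simulated library sizes.
Marginal-parameter recovery is checked on a single 6000-spot region: at a
mean count of about 3 per spot the Poisson layer keeps the
latent-variance posterior wide, so a large region is what makes a 10%
recovery check about the estimator rather than about sampling noise.

## Known limitations

* The BR-test's observed statistic pools Pearson correlations across
  regions on uncentered data; when regions differ strongly in mean *and*
  the scope pooling is used, the pooled correlation absorbs some
  mean-driven association. The permutation scheme centers regions before
  permuting, which keeps the null calibrated in the scenarios studied
  here, but extreme mean differences between regions deserve a look at
  `correlation_field()` output before interpreting a BR call.
* Bandwidth is global and isotropic; adaptive or anisotropic smoothing is
  out of scope.
* Permutation p values are the only inference offered; with the default
  $g = 10{,}000$ the smallest reportable p value is $10^{-4}$.
* `estimate_marginals()` assumes counts within a region are exchangeable
  draws from one Poisson-lognormal; strong within-region expression
  gradients violate this and bias $\sigma^2$ upward.
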
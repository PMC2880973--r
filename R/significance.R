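# Error-model fitting, per-gene/per-condition lambda likelihood-ratio
# statistics, the consecutive-condition persistence filter, and threshold
# sweep tables.
#
# Model: an observed (oriented, non-logged) expression ratio x for a gene
# with true ratio mu is x = mu * (1 + e_mult) + e_add with independent
# Gaussian errors, so Var(x | mu) = sigma_add^2 + mu^2 * sigma_mult^2.
# lambda is the generalized likelihood-ratio statistic (1 df) for
# H0: mu = 1 (no change between test and reference channels) against mu
# free, evaluated at globally estimated error-model parameters.

var_model <- function(mu, params) params$sigma_add^2 + (mu * params$sigma_mult)^2

#' Fit the additive + multiplicative error model
#'
#' Estimates `(sigma_add, sigma_mult)` by maximum likelihood from replicated
#' ratio observations across many genes.  Per-gene true ratios are profiled
#' out with their plug-in sample means; the variance parameters then
#' maximise the chi-square likelihood of the per-gene residual sums of
#' squares under `Var(x|mu) = sigma_add^2 + mu^2 sigma_mult^2`.
#'
#' @param replicated_obs numeric matrix of oriented non-logged ratios, one
#'   row per gene (or gene-condition), columns replicate observations; `NA`
#'   allowed.  At least 100 rows with >= 2 non-missing replicates required.
#' @param max_iter iteration cap handed to the optimizer.
#' @return An object of class `error_params`: list with `sigma_add`,
#'   `sigma_mult`, `converged`, `degenerate` (both parameters at the lower
#'   bound, e.g. noise-free input), `n_genes`, `loglik`.
#' @examples
#' set.seed(1)
#' mu <- 10^runif(500, -1, 1)
#' x <- sapply(1:4, function(i) mu * (1 + rnorm(500, 0, 0.1)) + rnorm(500, 0, 0.05))
#' estimate_error_params(x)
#' @export
estimate_error_params <- function(replicated_obs, max_iter = 500L) {
  x <- as.matrix(replicated_obs)
  nrep <- rowSums(!is.na(x))
  keep <- nrep >= 2
  if (sum(keep) < 100)
    stop("need at least 100 genes with >= 2 replicate observations")
  x <- x[keep, , drop = FALSE]
  nrep <- nrep[keep]
  m <- rowMeans(x, na.rm = TRUE)
  ss <- rowSums((x - m)^2, na.rm = TRUE)
  floor_sd <- 1e-6
  if (all(ss < 1e-24)) {
    return(structure(list(sigma_add = floor_sd, sigma_mult = floor_sd,
                          converged = TRUE, degenerate = TRUE,
                          n_genes = length(m), loglik = Inf),
                     class = "error_params"))
  }
  nll <- function(theta) {
    p <- list(sigma_add = exp(theta[1]), sigma_mult = exp(theta[2]))
    s2 <- var_model(m, p)
    sum((nrep - 1) / 2 * log(s2) + ss / (2 * s2))
  }
  s0 <- sqrt(mean(ss / (nrep - 1)))
  fit <- stats::optim(log(c(s0 / 2 + floor_sd, s0 / 2 / mean(abs(m)) + floor_sd)),
                      nll, method = "Nelder-Mead",
                      control = list(maxit = max_iter, reltol = 1e-12))
  if (fit$convergence != 0)
    stop(sprintf(paste("error-model fit did not converge within %d iterations;",
                       "last iterate sigma_add=%.4g sigma_mult=%.4g"),
                 max_iter, exp(fit$par[1]), exp(fit$par[2])))
  structure(list(sigma_add = max(exp(fit$par[1]), floor_sd),
                 sigma_mult = max(exp(fit$par[2]), floor_sd),
                 converged = TRUE,
                 degenerate = all(exp(fit$par) <= 10 * floor_sd),
                 n_genes = length(m), loglik = -fit$value),
            class = "error_params")
}

#' @export
print.error_params <- function(x, ...) {
  cat(sprintf("Error model: sigma_add = %.4g, sigma_mult = %.4g (%d genes%s)\n",
              x$sigma_add, x$sigma_mult, x$n_genes,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Lambda significance statistic for one gene and condition
#'
#' The likelihood-ratio statistic `lambda = 2 (l1 - l0)` testing equal true
#' abundance in the test and reference channels (true ratio `mu = 1`)
#' against a free `mu`, under the fitted error model with the variance
#' profiled at the gene's observed mean level `sigma^2(xbar)`.  With a
#' level-plugged common variance the mean MLE under the alternative is the
#' sample mean and lambda has the closed form
#' `n (xbar - 1)^2 / sigma^2(xbar)`: exactly zero when the replicate ratios
#' average to 1, strictly increasing in the distance of the mean ratio from
#' 1 at fixed noise, and approximately chi-square with 1 degree of freedom
#' under the null.
#'
#' @param gene_obs numeric vector of >= 2 oriented non-logged ratio
#'   observations (replicates of one gene at one condition); `NA` dropped.
#' @param params an [estimate_error_params()] result.
#' @return lambda, a single non-negative number (`NA` if fewer than 2
#'   usable observations).
#' @export
lambda_statistic <- function(gene_obs, params) {
  if (missing(params) || !inherits(params, "error_params"))
    stop("error-model params are required")
  x <- gene_obs[!is.na(gene_obs)]
  if (length(x) < 2) return(NA_real_)
  m <- mean(x)
  length(x) * (m - 1)^2 / var_model(m, params)
}

#' Lambda matrix for a whole expression matrix
#'
#' Computes [lambda_statistic()] for every gene at every condition, where a
#' condition is a (strain, sample_index) pair and its replicate observations
#' are all samples of that strain and index (duplicate cultures and dye
#' orientations).  The resulting value is assigned to every sample column of
#' its condition, keeping the lambda matrix aligned with the ratio matrix.
#'
#' @param x an [expression_matrix()].
#' @param params an [estimate_error_params()] result; if missing, fitted
#'   from the matrix itself via [estimate_error_params()] on per-condition
#'   replicate sets.
#' @return an `expression_matrix` equal to `x` with its `lambda` field
#'   populated.
#' @export
compute_lambda <- function(x, params = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  ratios <- oriented_ratios(x, logged = FALSE)
  cond <- paste(x$samples$strain, x$samples$sample_index, sep = "#")
  groups <- split(seq_len(ncol(ratios)), cond)
  if (is.null(params)) {
    obs <- do.call(rbind, lapply(groups, function(j) {
      r <- ratios[, j, drop = FALSE]
      ncolmax <- max(lengths(groups))
      cbind(r, matrix(NA_real_, nrow(r), ncolmax - ncol(r)))
    }))
    params <- estimate_error_params(obs)
  }
  lam <- matrix(NA_real_, nrow(ratios), ncol(ratios),
                dimnames = dimnames(ratios))
  for (j in groups) {
    r <- ratios[, j, drop = FALSE]
    nobs <- rowSums(!is.na(r))
    m <- rowMeans(r, na.rm = TRUE)
    vals <- ifelse(nobs >= 2, nobs * (m - 1)^2 / var_model(m, params), NA_real_)
    lam[, j] <- vals
  }
  x$lambda <- lam
  x
}

#' Genes persistently significant across consecutive conditions
#'
#' A gene is retained iff, within some strain, it has a run of at least `k`
#' consecutive growth-ordered samples (duplicate cultures interleaved in OD
#' order) whose lambda values are all *strictly* greater than `lambda0`.
#' Missing lambda values break a run.  Results from different strains are
#' unioned.
#'
#' @param lam numeric matrix of lambda values, genes x ordered samples, or
#'   an [expression_matrix()] with lambda attached.
#' @param lambda0 significance threshold (default 15).
#' @param k run length (default 4); must not exceed the number of samples of
#'   any scanned strain.
#' @param groups optional vector assigning each column to a scan group
#'   (defaults to the strain when `lam` is an expression matrix, otherwise
#'   one group).
#' @return character vector of retained gene ids.
#' @export
persistent_significant_set <- function(lam, lambda0 = 15, k = 4, groups = NULL) {
  if (inherits(lam, "expression_matrix")) {
    if (is.null(lam$lambda)) stop("expression matrix has no lambda values")
    if (is.null(groups)) groups <- lam$samples$strain
    lam <- lam$lambda
  }
  lam <- as.matrix(lam)
  if (is.null(groups)) groups <- rep("all", ncol(lam))
  if (k < 1) stop("k must be >= 1")
  if (k > max(table(groups)))
    stop("k exceeds the number of conditions in every group")
  hits <- rep(FALSE, nrow(lam))
  for (g in unique(groups)) {
    sub <- lam[, groups == g, drop = FALSE]
    if (ncol(sub) < k) next
    ok <- !is.na(sub) & sub > lambda0
    run <- matrix(0L, nrow(ok), ncol(ok))
    run[, 1] <- ok[, 1]
    for (j in seq_len(ncol(ok))[-1])
      run[, j] <- ifelse(ok[, j], run[, j - 1] + 1L, 0L)
    hits <- hits | apply(run, 1, max) >= k
  }
  rownames(lam)[hits]
}

#' Threshold sweep table
#'
#' Counts genes passing [persistent_significant_set()] for every combination
#' of lambda threshold and run length, the tabulation used to report how the
#' significant-gene count grows as the filter is relaxed.
#'
#' @param lam lambda matrix or [expression_matrix()] (see
#'   [persistent_significant_set()]).
#' @param lambda0_list,k_list non-empty numeric vectors of thresholds and
#'   run lengths.
#' @param N total number of genes in the genome used for the fraction
#'   column; defaults to the number of rows of `lam`, and must not be
#'   smaller than it.
#' @param groups optional column scan groups (see
#'   [persistent_significant_set()]).
#' @return An object of class `sweep_table`: data frame with columns
#'   `lambda0`, `k`, `gene_count`, `fraction`.  Counts are checked to be
#'   non-increasing in `lambda0` at fixed `k` and in `k` at fixed `lambda0`.
#' @export
threshold_sweep <- function(lam, lambda0_list, k_list, N = NULL, groups = NULL) {
  if (!length(lambda0_list) || !length(k_list))
    stop("lambda0_list and k_list must be non-empty")
  nr <- if (inherits(lam, "expression_matrix")) nrow(lam$log10_ratio) else nrow(lam)
  if (is.null(N)) N <- nr
  if (N < nr) stop("N is smaller than the observed gene count")
  grid <- expand.grid(lambda0 = lambda0_list, k = k_list)
  grid$gene_count <- mapply(function(l0, k)
    length(persistent_significant_set(lam, l0, k, groups)),
    grid$lambda0, grid$k)
  grid$fraction <- grid$gene_count / N
  for (k in unique(grid$k)) {
    sub <- grid[grid$k == k, ]
    if (is.unsorted(-sub$gene_count[order(sub$lambda0)]))
      stop("internal error: counts not monotone in lambda0")
  }
  for (l0 in unique(grid$lambda0)) {
    sub <- grid[grid$lambda0 == l0, ]
    if (is.unsorted(-sub$gene_count[order(sub$k)]))
      stop("internal error: counts not monotone in k")
  }
  structure(grid, class = c("sweep_table", "data.frame"))
}
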
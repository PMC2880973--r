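# Shape metrics from binary cell masks, two-component Gaussian mixture
# fits of circularity, per-timepoint population trajectories, and the
# gas-vesicle median-intensity index.

#' Shape metrics for one cell mask
#'
#' Computes area (pixel count), perimeter, circularity and ellipse axes for
#' a single-cell binary mask.  The perimeter is the corner-corrected
#' chain-length estimator: the 8-connected boundary contour is traced and
#' axis steps count 1 while diagonal steps count sqrt(2), which keeps a
#' rasterized disc near circularity 1 instead of overshooting.  Circularity
#' is `C = min(1, 4*pi*A / P^2)`; axes come from the second central moments
#' of the pixel coordinates (major/minor = 4 sd along the principal axes,
#' the ellipse-of-equal-moments convention).
#'
#' @param mask binary (0/1 or logical) matrix containing exactly one
#'   connected component of at least 20 pixels.
#' @param intensity optional numeric matrix of the same shape; its mean over
#'   the mask is reported as `mean_intensity`.
#' @param cell_id,timepoint identifiers copied into the output row.
#' @return one-row data frame with columns `cell_id`, `timepoint`, `area`,
#'   `perimeter`, `circularity`, `major`, `minor`, `mean_intensity`.
#' @export
shape_metrics <- function(mask, intensity = NULL, cell_id = "cell",
                          timepoint = 1L) {
  m <- matrix(as.integer(as.logical(mask)), nrow(mask), ncol(mask))
  area <- sum(m)
  if (area < 20) stop("mask must contain at least 20 pixels")
  lab <- EBImage::bwlabel(m)
  if (max(lab) != 1) stop("mask must contain exactly one connected component")
  oc <- EBImage::ocontour(lab)[[1]]
  d <- rbind(diff(oc), oc[1, ] - oc[nrow(oc), ])
  steps <- abs(d[, 1]) + abs(d[, 2])
  per <- sum(ifelse(steps == 2, sqrt(2), 1))
  circ <- min(1, 4 * pi * area / per^2)
  xy <- which(m == 1, arr.ind = TRUE)
  cv <- stats::cov(xy) * (nrow(xy) - 1) / nrow(xy)
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  mi <- if (is.null(intensity)) NA_real_ else mean(intensity[m == 1])
  data.frame(cell_id = cell_id, timepoint = timepoint, area = area,
             perimeter = per, circularity = circ,
             major = 4 * sqrt(max(ev[1], 0)), minor = 4 * sqrt(max(ev[2], 0)),
             mean_intensity = mi, stringsAsFactors = FALSE)
}

#' Fit a two-component Gaussian mixture to circularity values
#'
#' Expectation-maximisation for a two-component univariate Gaussian mixture,
#' the model used to decompose a cell population into a low-circularity
#' (rod) and a high-circularity (spherical) component.  Components are
#' ordered `mu1 <= mu2` on output, so component 1 is always the rod
#' component.  Initialisation splits the data at the 40th percentile (a
#' rod-heavy prior); standard deviations are floored at 1e-3 against
#' collapse.  Convergence is declared when the log-likelihood gain drops
#' below `tol`; the per-iteration log-likelihood trace is returned and is
#' non-decreasing by construction of EM.
#'
#' @param circularities numeric values in (0, 1]; at least `min_n` required.
#' @param init `"quantile"` (default) or `"random"` (requires `seed`).
#' @param max_iter EM iteration cap (default 500).
#' @param tol log-likelihood convergence tolerance (default 1e-8).
#' @param seed optional seed for random initialisation.
#' @param min_n minimum population size (default 50, the usual minimum for a
#'   per-timepoint morphology estimate).
#' @param allow_small permit `n < min_n` with a warning instead of an error.
#' @return An object of class `mixture_fit`: list with `w` (weights, sums to
#'   1), `mu` (`mu[1] <= mu[2]`), `sigma`, `loglik` (final), `loglik_trace`,
#'   `iterations`, `converged`, `separation` (Ashman's D,
#'   `sqrt(2) |mu2 - mu1| / sqrt(sigma1^2 + sigma2^2)`), `overlap` (`TRUE`
#'   when D < 2, i.e. the components do not form a clean bimodal split),
#'   `n`, and `responsibility` (probability each cell belongs to
#'   component 2).
#' @examples
#' set.seed(2)
#' x <- c(rnorm(300, 0.35, 0.08), rnorm(700, 0.85, 0.05))
#' x <- pmin(pmax(x, 1e-3), 1)
#' fit_two_component_mixture(x)
#' @export
fit_two_component_mixture <- function(circularities, init = c("quantile", "random"),
                                      max_iter = 500L, tol = 1e-8, seed = NULL,
                                      min_n = 50L, allow_small = FALSE,
                                      start = NULL) {
  x <- circularities[!is.na(circularities)]
  n <- length(x)
  if (n < min_n) {
    if (!allow_small) stop("need at least ", min_n, " cells (got ", n, ")")
    warning("fitting mixture on only ", n, " cells")
  }
  if (length(unique(x)) == 1) stop("all circularity values identical")
  init <- match.arg(init)
  sd_floor <- 1e-3
  if (!is.null(start)) {
    w <- start$w; mu <- start$mu; sig <- pmax(start$sigma, sd_floor)
  } else if (init == "quantile") {
    q <- stats::quantile(x, 0.4, names = FALSE)
    lo <- x[x <= q]; hi <- x[x > q]
    if (!length(hi)) { lo <- x[x < max(x)]; hi <- x[x == max(x)] }
    w <- c(length(lo), length(hi)) / n
    mu <- c(mean(lo), mean(hi))
    sig <- pmax(c(stats::sd(lo), stats::sd(hi)), sd_floor, na.rm = TRUE)
  } else {
    if (is.null(seed)) stop("random initialisation requires a seed")
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    mu <- sort(sample(x, 2))
    w <- c(0.5, 0.5)
    sig <- rep(max(stats::sd(x) / 2, sd_floor), 2)
  }
  sig[is.na(sig)] <- sd_floor
  loglik <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sig[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sig[2])
    tot <- d1 + d2
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    if (is.finite(loglik) && ll - loglik < tol) { converged <- TRUE; loglik <- ll; break }
    loglik <- ll
    g2 <- d2 / tot
    n2 <- sum(g2); n1 <- n - n2
    if (n1 < 1e-8 || n2 < 1e-8) { converged <- TRUE; break }  # degenerate weight
    w <- c(n1, n2) / n
    mu <- c(sum((1 - g2) * x) / n1, sum(g2 * x) / n2)
    sig <- pmax(sqrt(c(sum((1 - g2) * (x - mu[1])^2) / n1,
                       sum(g2 * (x - mu[2])^2) / n2)), sd_floor)
  }
  if (!converged)
    warning("EM did not converge within ", max_iter, " iterations")
  g2 <- w[2] * stats::dnorm(x, mu[2], sig[2]) /
    pmax(w[1] * stats::dnorm(x, mu[1], sig[1]) +
         w[2] * stats::dnorm(x, mu[2], sig[2]), .Machine$double.xmin)
  if (mu[1] > mu[2]) {
    mu <- rev(mu); sig <- rev(sig); w <- rev(w); g2 <- 1 - g2
  }
  # Ashman's D < 2 marks components too close to be a clean bimodal split
  ashman_d <- sqrt(2) * abs(mu[2] - mu[1]) / sqrt(sig[1]^2 + sig[2]^2)
  structure(
    list(w = w, mu = mu, sigma = sig, loglik = loglik, loglik_trace = trace,
         iterations = length(trace), converged = converged,
         overlap = ashman_d < 2, separation = ashman_d, n = n,
         responsibility = g2),
    class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(paste0("Two-component mixture (n = %d): w = (%.3f, %.3f), ",
                     "mu = (%.3f, %.3f), sigma = (%.3f, %.3f)%s\n"),
              x$n, x$w[1], x$w[2], x$mu[1], x$mu[2], x$sigma[1], x$sigma[2],
              if (x$overlap) " [overlapping]" else ""))
  invisible(x)
}

#' Morphology trajectory across a growth curve
#'
#' Fits the two-component circularity mixture at every timepoint of a
#' per-cell morphology table, warm-starting each fit from the previous
#' timepoint's parameters, and aligns the fits with the growth curve's
#' OD600 values.  The derived series `w2(t)` (fraction of spherical cells)
#' and `mu2(t)` track how the population shape composition changes through
#' growth.
#'
#' @param cells data frame of per-cell measurements (see
#'   [read_morphology()]); `timepoint` values index the growth curve's
#'   sampling points.
#' @param growth a [growth_curve()] covering every timepoint in `cells`.
#' @param min_n minimum cells per timepoint (default 50).
#' @param ... further arguments to [fit_two_component_mixture()].
#' @return An object of class `morphology_trajectory`: list with `table`
#'   (data frame per timepoint: `timepoint`, `od600`, `w1`, `w2`, `mu1`,
#'   `mu2`, `sigma1`, `sigma2`, `n`, `converged`) and `fits` (list of
#'   `mixture_fit`).
#' @export
population_trajectory <- function(cells, growth, min_n = 50L, ...) {
  stopifnot(inherits(growth, "growth_curve"))
  tps <- sort(unique(cells$timepoint))
  if (any(tps < 1 | tps > length(growth$time_h)))
    stop("timepoint missing from growth curve")
  fits <- list()
  prev <- NULL
  rows <- lapply(tps, function(tp) {
    x <- cells$circularity[cells$timepoint == tp]
    fit <- fit_two_component_mixture(x, min_n = min_n, start = prev, ...)
    prev <<- list(w = fit$w, mu = fit$mu, sigma = fit$sigma)
    fits[[as.character(tp)]] <<- fit
    data.frame(timepoint = tp, od600 = growth$od600[tp],
               w1 = fit$w[1], w2 = fit$w[2], mu1 = fit$mu[1], mu2 = fit$mu[2],
               sigma1 = fit$sigma[1], sigma2 = fit$sigma[2],
               n = fit$n, converged = fit$converged)
  })
  structure(list(table = do.call(rbind, rows), fits = fits, growth = growth),
            class = "morphology_trajectory")
}

#' @export
print.morphology_trajectory <- function(x, ...) {
  cat("Morphology trajectory over", nrow(x$table), "timepoints\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Gas-vesicle index of a cell population
#'
#' The median of per-cell mean pixel intensities at one timepoint -- a
#' robust population-level proxy for gas-vesicle content, since
#' vesicle-rich cells scatter light and appear bright.
#'
#' @param intensities numeric vector of per-cell mean intensities
#'   (non-empty; `NA` dropped).
#' @return the median, in grayscale units.
#' @export
gas_vesicle_index <- function(intensities) {
  x <- intensities[!is.na(intensities)]
  if (!length(x)) stop("no intensity values supplied")
  stats::median(x)
}
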
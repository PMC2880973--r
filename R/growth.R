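# Growth-curve quantification and phase annotation.

#' Root-mean-square distance between replicate growth curves
#'
#' Agreement between two replicate cultures is summarised as the RMSD of
#' their OD600 values at matched sampling points.  Points are matched by
#' sampling time within `time_tol` hours; no interpolation is performed --
#' replicate flasks sampled on a shared design are compared point by point.
#'
#' @param a,b [growth_curve()] objects.
#' @param time_tol tolerance (hours) for declaring two sampling times
#'   matched.
#' @return RMSD in absorbance units (a single non-negative number).
#' @examples
#' a <- growth_curve("wt", "A", 0:5, c(.02, .04, .08, .16, .3, .5))
#' b <- growth_curve("wt", "B", 0:5, c(.02, .05, .09, .15, .32, .48))
#' replicate_rmsd(a, b)
#' @export
replicate_rmsd <- function(a, b, time_tol = 1e-6) {
  stopifnot(inherits(a, "growth_curve"), inherits(b, "growth_curve"))
  idx <- outer(a$time_h, b$time_h, function(x, y) abs(x - y) <= time_tol)
  ia <- which(rowSums(idx) > 0)
  ib <- apply(idx[ia, , drop = FALSE], 1, which.max)
  if (!length(ia)) stop("no matched timepoints between the two curves")
  sqrt(mean((a$od600[ia] - b$od600[ib])^2))
}

#' Estimate specific growth rates along a curve
#'
#' The specific growth rate mu(t) = d ln(OD)/dt is estimated by central
#' finite differences on log OD at interior points and one-sided differences
#' at the ends; on a pure exponential this is exact.  An optional odd-width
#' moving average can pre-smooth log OD for noisy curves.
#'
#' @param curve a [growth_curve()] with at least 4 points.
#' @param smooth_window odd integer moving-average width applied to log OD
#'   before differencing; 1 (default) disables smoothing.
#' @return An object of class `growth_fit`: list with `mu` (per-hour, one
#'   value per timepoint), `mu_max`, `t_mu_max` (hours), `doubling_time`
#'   (hours, `NA` when `mu_max <= 0`), and the source `curve`.
#' @examples
#' gc <- growth_curve("wt", "A", 0:10, 0.02 * exp(0.2 * (0:10)))
#' fit <- estimate_growth_rates(gc)
#' fit$mu_max          # 0.2/h
#' fit$doubling_time   # log(2)/0.2
#' @export
estimate_growth_rates <- function(curve, smooth_window = 1L) {
  stopifnot(inherits(curve, "growth_curve"))
  n <- length(curve$time_h)
  if (n < 4) stop("at least 4 points are required")
  if (any(curve$od600 <= 0)) stop("all OD values must be positive")
  if (smooth_window %% 2 != 1 || smooth_window < 1)
    stop("smooth_window must be an odd positive integer")
  t <- curve$time_h
  l <- log(curve$od600)
  if (smooth_window > 1) {
    h <- (smooth_window - 1) / 2
    l <- vapply(seq_len(n), function(i)
      mean(l[max(1, i - h):min(n, i + h)]), numeric(1))
  }
  mu <- numeric(n)
  mu[1] <- (l[2] - l[1]) / (t[2] - t[1])
  mu[n] <- (l[n] - l[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    mu[i] <- (l[i + 1] - l[i - 1]) / (t[i + 1] - t[i - 1])
  }
  mu_max <- max(mu)
  structure(
    list(mu = mu, mu_max = mu_max, t_mu_max = t[which.max(mu)],
         doubling_time = if (mu_max > 0) log(2) / mu_max else NA_real_,
         curve = curve),
    class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Growth fit: mu_max = %.4g /h at t = %.2f h; doubling time %s h\n",
              x$mu_max, x$t_mu_max,
              if (is.na(x$doubling_time)) "undefined"
              else sprintf("%.3g", x$doubling_time)))
  invisible(x)
}

#' Partition a growth curve into four phases
#'
#' Labels every sampling point as `EARLY`, `EXPONENTIAL`, `TRANSITION` or
#' `STATIONARY` from thresholds on the specific growth rate relative to its
#' maximum.  The EXPONENTIAL block is the contiguous run around the point of
#' maximal mu where `mu >= f_exp * mu_max`; everything before it is EARLY;
#' the trailing run with `mu <= f_stat * mu_max` is STATIONARY; points in
#' between are TRANSITION.  The labels always form contiguous blocks in that
#' order (empty blocks allowed).
#'
#' The fraction thresholds are a package convention: the growth literature
#' names these phases without operational boundaries, so the cutoffs are
#' explicit, configurable and recorded in the result.
#'
#' @param fit a [estimate_growth_rates()] result.
#' @param curve the curve the fit was computed from (consistency-checked).
#' @param f_exp fraction of `mu_max` above which a point counts as
#'   exponential (default 0.5).
#' @param f_stat fraction of `mu_max` below which a trailing point counts as
#'   stationary (default 0.1); must satisfy `0 < f_stat < f_exp < 1`.
#' @return An object of class `phase_annotation`: list with `labels`
#'   (character vector over timepoints), `time_h`, `od600`, `boundaries`
#'   (named numeric, phase start times), `f_exp`, `f_stat`.
#' @export
annotate_phases <- function(fit, curve = fit$curve, f_exp = 0.5, f_stat = 0.1) {
  stopifnot(inherits(fit, "growth_fit"), inherits(curve, "growth_curve"))
  if (!isTRUE(all.equal(fit$curve$od600, curve$od600)))
    stop("fit was not derived from this curve")
  if (!(f_stat > 0 && f_stat < f_exp && f_exp < 1))
    stop("require 0 < f_stat < f_exp < 1")
  mu <- fit$mu
  n <- length(mu)
  if (fit$mu_max <= 0) stop("no exponential phase detected (mu_max <= 0)")
  peak <- which.max(mu)
  lo <- peak
  while (lo > 1 && mu[lo - 1] >= f_exp * fit$mu_max) lo <- lo - 1
  hi <- peak
  while (hi < n && mu[hi + 1] >= f_exp * fit$mu_max) hi <- hi + 1
  labels <- rep("TRANSITION", n)
  labels[seq_len(n) < lo] <- "EARLY"
  labels[lo:hi] <- "EXPONENTIAL"
  st <- n + 1
  while (st > hi + 1 && mu[st - 1] <= f_stat * fit$mu_max) st <- st - 1
  if (st <= n) labels[st:n] <- "STATIONARY"
  starts <- vapply(c("EARLY", "EXPONENTIAL", "TRANSITION", "STATIONARY"),
                   function(p) {
                     i <- which(labels == p)
                     if (length(i)) curve$time_h[min(i)] else NA_real_
                   }, numeric(1))
  structure(
    list(labels = labels, time_h = curve$time_h, od600 = curve$od600,
         boundaries = starts, f_exp = f_exp, f_stat = f_stat),
    class = "phase_annotation")
}

#' @export
print.phase_annotation <- function(x, ...) {
  tab <- table(factor(x$labels, levels = phase_levels()))
  cat("Phase annotation (f_exp =", x$f_exp, ", f_stat =", x$f_stat, "):",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

phase_levels <- function() c("EARLY", "EXPONENTIAL", "TRANSITION", "STATIONARY")

#' Map expression samples to growth phases
#'
#' Looks up the phase label of each sample of an expression matrix from the
#' phase annotation of its culture, matching samples to annotation points by
#' `sample_index`.
#'
#' @param x an [expression_matrix()].
#' @param phases a [annotate_phases()] result covering the sampled points.
#' @return character vector of phase labels, one per sample column.
#' @export
sample_phases <- function(x, phases) {
  stopifnot(inherits(x, "expression_matrix"), inherits(phases, "phase_annotation"))
  idx <- x$samples$sample_index
  if (any(idx < 1 | idx > length(phases$labels)))
    stop("phase annotation does not cover all sample indices")
  phases$labels[idx]
}
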
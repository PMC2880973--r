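# Phase-level aggregation of metabolite features, the significance/fold
# filter, and transcript-metabolite concordance scoring.

metabolite_phases <- function() c("EARLY", "EXPONENTIAL", "STATIONARY")

# population-sd standardization to mean 0, sd 1
standardize3 <- function(v) {
  s <- sqrt(mean((v - mean(v))^2))
  if (s == 0) stop("zero variance across phases")
  (v - mean(v)) / s
}

#' Three-phase expression profile of a gene set
#'
#' Averages the non-logged expression ratio of a gene set within each of the
#' EARLY, EXPONENTIAL and STATIONARY phases and standardizes the three phase
#' means to mean 0, sd 1 (population sd).  The standardized profile is the
#' transcript-side input to [concordance_score()].
#'
#' @param x an [expression_matrix()].
#' @param phase_labels per-sample phase labels (see [sample_phases()]);
#'   TRANSITION samples are ignored.
#' @param genes character vector of gene ids to average.
#' @return named numeric vector of length 3 (standardized phase profile).
#' @export
phase_aggregate <- function(x, phase_labels, genes) {
  stopifnot(inherits(x, "expression_matrix"))
  miss <- setdiff(genes, x$gene_ids)
  if (length(miss)) stop("unknown gene id: ", miss[1])
  r <- oriented_ratios(x, logged = FALSE)[genes, , drop = FALSE]
  prof <- vapply(metabolite_phases(), function(p) {
    j <- which(phase_labels == p)
    if (!length(j)) stop("no samples in phase ", p)
    mean(rowMeans(r[, j, drop = FALSE], na.rm = TRUE))
  }, numeric(1))
  standardize3(prof)
}

per_feature_stats <- function(features) {
  ph <- metabolite_phases()
  split_f <- split(features, features$feature_id)
  out <- lapply(split_f, function(d) {
    ab <- lapply(ph, function(p) d$abundance[d$phase == p])
    names(ab) <- ph
    means <- vapply(ab, mean, numeric(1))
    list(mz = d$mz[1], rt_min = d$rt_min[1], abundance = ab, means = means)
  })
  out[unique(features$feature_id)]
}

#' Filter metabolite features by significance and fold change
#'
#' Retains a feature iff a Welch t-test on log-transformed abundances
#' between the EARLY and STATIONARY phases gives `p < p_threshold`, and the
#' ratio of phase mean abundances (in either direction) is at least
#' `min_fold` (inclusive).  A zero phase mean opposite a non-zero one counts
#' as infinite fold change and passes the fold criterion (logged via
#' `message`).  Zero abundances entering the t-test are offset by half the
#' smallest positive abundance of the feature before logging.
#'
#' @param features long-format metabolite table (see [read_metabolites()])
#'   with >= 2 replicates in EARLY and STATIONARY for every feature.
#' @param p_threshold significance cutoff (default 0.001, strict `<`).
#' @param min_fold minimum early-to-stationary fold change (default 3,
#'   inclusive `>=`).
#' @return data frame with one row per feature: `feature_id`, `mz`,
#'   `rt_min`, `mean_early`, `mean_exponential`, `mean_stationary`, `fold`,
#'   `p`, `retained`.
#' @export
filter_significant_features <- function(features, p_threshold = 0.001,
                                        min_fold = 3) {
  st <- per_feature_stats(features)
  rows <- lapply(names(st), function(id) {
    f <- st[[id]]
    e <- f$abundance$EARLY; s <- f$abundance$STATIONARY
    if (length(e) < 2 || length(s) < 2)
      stop("feature ", id, " needs >= 2 replicates in EARLY and STATIONARY")
    me <- mean(e); ms <- mean(s)
    if (xor(me == 0, ms == 0)) {
      fold <- Inf
      message("feature ", id, ": zero phase mean, fold treated as infinite")
    } else if (me == 0 && ms == 0) {
      fold <- 1
    } else {
      fold <- max(ms / me, me / ms)
    }
    eps <- min(c(e[e > 0], s[s > 0], 1)) / 2
    le <- log(ifelse(e > 0, e, eps)); ls <- log(ifelse(s > 0, s, eps))
    p <- if (stats::sd(le) == 0 && stats::sd(ls) == 0) {
      # replicates exactly constant in both phases: perfect separation when
      # the means differ, no evidence when they agree
      if (isTRUE(all.equal(mean(le), mean(ls)))) 1 else 0
    } else {
      tryCatch(stats::t.test(le, ls)$p.value, error = function(err) 1)
    }
    data.frame(feature_id = id, mz = f$mz, rt_min = f$rt_min,
               mean_early = me, mean_exponential = f$means[["EXPONENTIAL"]],
               mean_stationary = ms, fold = fold, p = p,
               retained = p < p_threshold & fold >= min_fold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Concordance between a metabolite and a gene-group phase profile
#'
#' Pearson correlation between two standardized three-phase profiles
#' (EARLY, EXPONENTIAL, STATIONARY).  With three values this is the natural
#' measure of how well a transcript group's phase pattern predicts a
#' metabolite's phase pattern; it is symmetric in its arguments, bounded in
#' [-1, 1], and invariant to affine rescaling of either profile.
#'
#' @param metabolite_profile,gene_profile numeric vectors of length 3 with
#'   finite values and non-zero variance (standardization is applied
#'   internally, so raw phase means are accepted).
#' @param method `"pearson"` (default) or `"spearman"` for a rank-based
#'   alternative.
#' @return correlation in [-1, 1].
#' @examples
#' concordance_score(c(1, 0.1, 1), c(2, 0.3, 2))   # same shape: 1
#' @export
concordance_score <- function(metabolite_profile, gene_profile,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  a <- as.numeric(metabolite_profile); b <- as.numeric(gene_profile)
  if (length(a) != 3 || length(b) != 3 || !all(is.finite(c(a, b))))
    stop("profiles must be 3 finite phase values")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero-variance profile")
  stats::cor(a, b, method = method)
}

#' Three-phase abundance profile of one metabolite feature
#'
#' @param features long-format metabolite table.
#' @param feature_id feature to extract.
#' @return standardized (mean 0, population sd 1) numeric vector of the
#'   three phase mean abundances.
#' @export
metabolite_profile <- function(features, feature_id) {
  st <- per_feature_stats(features[features$feature_id == feature_id, ])
  if (!length(st)) stop("unknown feature id: ", feature_id)
  standardize3(st[[1]]$means)
}
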
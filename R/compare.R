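# Fold-change estimation over the growth curve, permutation differential
# testing between strains, and the endpoint change test.

first_last_blocks <- function(x, strain = NULL, block = 4L) {
  stopifnot(inherits(x, "expression_matrix"))
  keep <- if (is.null(strain)) seq_len(ncol(x$log10_ratio))
          else which(x$samples$strain == strain)
  if (length(keep) < 2 * block)
    stop("need at least ", 2 * block, " samples (got ", length(keep), ")")
  list(first = keep[seq_len(block)],
       last = keep[seq(length(keep) - block + 1, length(keep))])
}

#' Fold change over the growth curve
#'
#' For each gene, the ratio of the average *non-logged* expression ratio
#' over the last four growth-ordered samples (replicates included) to the
#' average over the first four.  Samples follow the canonical
#' increasing-OD600 ordering of the expression matrix.
#'
#' @param x an [expression_matrix()] (stores log10 ratios).
#' @param genes optional character vector of gene ids (default: all).
#' @param strain optional strain to restrict the sample window to.
#' @param block number of samples in each end window (default 4).
#' @return named numeric vector of fold changes (always positive; 1 means
#'   no change, values > 1 mean higher late in growth).
#' @export
fold_change <- function(x, genes = NULL, strain = NULL, block = 4L) {
  idx <- first_last_blocks(x, strain, block)
  r <- oriented_ratios(x, logged = FALSE)
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(r))
    if (length(miss)) stop("unknown gene id: ", miss[1])
    r <- r[genes, , drop = FALSE]
  }
  rowMeans(r[, idx$last, drop = FALSE], na.rm = TRUE) /
    rowMeans(r[, idx$first, drop = FALSE], na.rm = TRUE)
}

# vectorized per-gene Welch t on rows of a and b (columns = samples)
welch_t_rows <- function(a, b, pooled = FALSE) {
  na <- rowSums(!is.na(a)); nb <- rowSums(!is.na(b))
  ma <- rowMeans(a, na.rm = TRUE); mb <- rowMeans(b, na.rm = TRUE)
  va <- rowSums((a - ma)^2, na.rm = TRUE) / pmax(na - 1, 1)
  vb <- rowSums((b - mb)^2, na.rm = TRUE) / pmax(nb - 1, 1)
  se2 <- if (pooled) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / pmax(na + nb - 2, 1)
    sp2 * (1 / na + 1 / nb)
  } else va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  t[se2 == 0] <- 0  # constant in both groups: no evidence either way
  t
}

#' Permutation t-test between two sample groups with false-significant-
#' proportion control
#'
#' Per-gene two-sample t statistics (Welch by default) on logged ratios,
#' with p-values from permutation of the group labels.  When the number of
#' distinct label arrangements is at most `n_perm` the full enumeration is
#' used and `p` is the exact fraction of arrangements (identity included)
#' with `|t*| >= |t|`; otherwise `n_perm` random permutations are drawn and
#' `p = (1 + #exceedances) / (n_perm + 1)`.
#'
#' The significant set is chosen by a permutation-estimated
#' false-significant-proportion step.  Candidate rejection sets are nested
#' by `|t|` among the genes with `p <= alpha`; for each set, the median over
#' permutations of the number of permuted statistics falling in its `|t|`
#' region estimates the expected null count, and the largest set whose
#' estimated false proportion does not exceed `max_false_prop` is declared
#' significant.
#'
#' @param groupA,groupB numeric matrices of logged ratios with identical
#'   rownames (genes x samples); at least 2 samples per group.
#' @param n_perm permutation budget (>= 100).
#' @param alpha overall critical p-value cutoff (default 0.01).
#' @param max_false_prop bound on the estimated proportion of false
#'   significants (default 0.01).
#' @param seed integer seed for sampled permutations.
#' @param pooled use the pooled-variance t instead of Welch.
#' @return An object of class `differential_result`: data frame with columns
#'   `gene`, `t`, `p`, `significant`, `fold_change` (non-logged
#'   `mean(10^A)/mean(10^B)`), plus attributes `n_perm_used`, `enumerated`,
#'   `p_cutoff`, `est_false_prop`.
#' @export
permutation_differential <- function(groupA, groupB, n_perm = 1000L,
                                     alpha = 0.01, max_false_prop = 0.01,
                                     seed = 1L, pooled = FALSE) {
  a <- as.matrix(groupA); b <- as.matrix(groupB)
  if (!identical(rownames(a), rownames(b)))
    stop("groupA and groupB must share gene rows")
  nA <- ncol(a); nB <- ncol(b)
  if (nA < 2 || nB < 2) stop("need at least 2 samples per group")
  if (n_perm < 100) stop("n_perm must be >= 100")
  pool <- cbind(a, b)
  n <- nA + nB
  n_arr <- choose(n, nA)
  enumerated <- n_arr <= n_perm
  if (enumerated) {
    sel <- utils::combn(n, nA)
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    sel <- replicate(n_perm, sample.int(n, nA))
  }
  tstar <- apply(sel, 2, function(ia)
    welch_t_rows(pool[, ia, drop = FALSE], pool[, -ia, drop = FALSE], pooled))
  tstar <- matrix(tstar, nrow = nrow(pool))  # genes x B
  B <- ncol(tstar)
  tobs <- welch_t_rows(a, b, pooled)
  const <- rowSums(abs(pool - rowMeans(pool)) > 0, na.rm = TRUE) == 0
  if (any(const))
    warning(sum(const), " gene(s) constant in both groups; p set to 1")
  exceed <- rowSums(abs(tstar) >= abs(tobs) - 1e-12)
  p <- if (enumerated) exceed / B else (1 + exceed) / (B + 1)
  p[const] <- 1
  # false-significant-proportion control: candidate rejection sets are
  # nested by |t| among genes passing alpha; the estimated null count is the
  # median over permutations of permuted statistics landing in the region,
  # and the largest set with estimated false proportion <= max_false_prop
  # wins
  at <- abs(tstar)
  passing <- p <= alpha
  sig <- rep(FALSE, length(p))
  p_cut <- 0
  fsp <- NA_real_
  for (T in sort(unique(abs(tobs)[passing]))) {
    rej <- passing & abs(tobs) >= T - 1e-12
    R <- sum(rej)
    Fb <- colSums(at >= T - 1e-12)
    est <- stats::median(Fb) / R
    if (est <= max_false_prop) {
      sig <- rej; p_cut <- max(p[rej]); fsp <- est
      break
    }
  }
  res <- data.frame(gene = rownames(a), t = tobs, p = p,
                    significant = sig,
                    fold_change = rowMeans(10^a, na.rm = TRUE) /
                                  rowMeans(10^b, na.rm = TRUE),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "n_perm_used") <- B
  attr(res, "enumerated") <- enumerated
  attr(res, "p_cutoff") <- p_cut
  attr(res, "est_false_prop") <- fsp
  class(res) <- c("differential_result", "data.frame")
  res
}

#' Endpoint change test (first four vs last four samples)
#'
#' Per-gene t-test on logged ratios comparing the first four against the
#' last four growth-ordered samples, with Benjamini-Hochberg false discovery
#' rate control.  A gene is flagged when its BH-adjusted p-value is at most
#' `fdr` and its raw p-value at most `alpha`.  Output mirrors a
#' gene/fold-change/flag endpoint table.
#'
#' @param x an [expression_matrix()].
#' @param alpha raw p-value threshold (default 0.05).
#' @param fdr false discovery rate (default 0.05).
#' @param strain optional strain restriction.
#' @param block end-window width (default 4).
#' @return data frame with columns `gene`, `fold_change`, `t`, `p`, `p_adj`,
#'   `flag` (0/1).
#' @export
endpoint_change_test <- function(x, alpha = 0.05, fdr = 0.05, strain = NULL,
                                 block = 4L) {
  idx <- first_last_blocks(x, strain, block)
  r <- oriented_ratios(x)
  a <- r[, idx$last, drop = FALSE]
  b <- r[, idx$first, drop = FALSE]
  t <- welch_t_rows(a, b)
  na <- rowSums(!is.na(a)); nb <- rowSums(!is.na(b))
  ma <- rowMeans(a, na.rm = TRUE); mb <- rowMeans(b, na.rm = TRUE)
  va <- rowSums((a - ma)^2, na.rm = TRUE) / pmax(na - 1, 1)
  vb <- rowSums((b - mb)^2, na.rm = TRUE) / pmax(nb - 1, 1)
  df <- (va / na + vb / nb)^2 /
    (va^2 / (na^2 * pmax(na - 1, 1)) + vb^2 / (nb^2 * pmax(nb - 1, 1)))
  p <- 2 * stats::pt(-abs(t), pmax(df, 1))
  p[is.na(p)] <- 1
  p_adj <- stats::p.adjust(p, "BH")
  data.frame(gene = rownames(r),
             fold_change = fold_change(x, strain = strain, block = block),
             t = t, p = p, p_adj = p_adj,
             flag = as.integer(p <= alpha & p_adj <= fdr),
             row.names = NULL, stringsAsFactors = FALSE)
}
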
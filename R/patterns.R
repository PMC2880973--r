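# Row normalization, K-means temporal pattern discovery, archetype
# classification, and replicon enrichment.

#' Row-normalize an expression matrix
#'
#' Centers and scales each gene row to mean 0 and standard deviation 1 over
#' its non-missing entries (population standard deviation, i.e. divisor n).
#' Row normalization puts genes of different absolute expression on a common
#' scale so that clustering groups them by temporal *shape* only.
#'
#' @param x numeric matrix (genes x samples) or an [expression_matrix()];
#'   in the latter case the oriented ratios are normalized.
#' @return numeric matrix of the same shape.  A row with fewer than 2
#'   non-missing values or zero variance raises an error naming the gene.
#' @examples
#' row_normalize(matrix(1:3, 1, dimnames = list("g1", NULL)))
#' @export
row_normalize <- function(x) {
  m <- if (inherits(x, "expression_matrix")) oriented_ratios(x) else as.matrix(x)
  nn <- rowSums(!is.na(m))
  if (any(nn < 2))
    stop("row with fewer than 2 non-missing values: ",
         rownames(m)[which(nn < 2)[1]])
  mu <- rowMeans(m, na.rm = TRUE)
  cent <- m - mu
  sd_pop <- sqrt(rowSums(cent^2, na.rm = TRUE) / nn)
  if (any(sd_pop == 0))
    stop("constant row (zero variance): ", rownames(m)[which(sd_pop == 0)[1]])
  cent / sd_pop
}

# k-means++-style farthest-point seeding from a seeded generator
kmeanspp_centers <- function(m, K) {
  n <- nrow(m)
  centers <- integer(K)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((m - matrix(m[centers[1], ], n, ncol(m), byrow = TRUE))^2)
  for (i in seq_len(K)[-1]) {
    p <- d2 / sum(d2)
    centers[i] <- if (sum(d2) > 0) sample.int(n, 1, prob = p) else sample.int(n, 1)
    nd <- rowSums((m - matrix(m[centers[i], ], n, ncol(m), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  m[centers, , drop = FALSE]
}

#' K-means clustering of normalized temporal profiles
#'
#' Runs Lloyd's K-means from `n_restarts` k-means++-style seedings drawn
#' from a seeded generator and keeps the assignment with the lowest total
#' within-cluster sum of squares (ties broken by the earliest restart).
#' Deterministic given `seed`.  Missing entries of the normalized matrix are
#' imputed as 0 (the row mean after normalization) before clustering.
#'
#' @param normalized numeric matrix from [row_normalize()].
#' @param K number of clusters, `1 <= K <=` number of genes.
#' @param seed integer seed.
#' @param n_restarts number of seedings (default 25).
#' @param iter_max Lloyd iteration cap per restart.
#' @return An object of class `archetype_result`: list with `cluster` (named
#'   integer vector gene -> cluster), `centroids` (K x samples matrix),
#'   `wss` (best total within-cluster SS), `K`, `seed`, `n_restarts`, and
#'   `labels` (`NULL` until [classify_archetypes()] is applied).
#' @export
cluster_profiles <- function(normalized, K, seed = 1L, n_restarts = 25L,
                             iter_max = 100L) {
  m <- as.matrix(normalized)
  if (K < 1) stop("K must be >= 1")
  if (K > nrow(m)) stop("K exceeds the number of genes")
  m[is.na(m)] <- 0
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- kmeanspp_centers(m, K)
    km <- suppressWarnings(
      stats::kmeans(m, centers = init, iter.max = iter_max, algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  cl <- best$cluster
  names(cl) <- rownames(m)
  structure(
    list(cluster = cl, centroids = best$centers, wss = best$tot.withinss,
         K = K, seed = seed, n_restarts = n_restarts, labels = NULL,
         delta = NULL),
    class = "archetype_result")
}

#' @export
print.archetype_result <- function(x, ...) {
  cat(sprintf("Archetype result: %d genes in K = %d clusters (WSS %.3g)\n",
              length(x$cluster), x$K, x$wss))
  if (!is.null(x$labels)) {
    tab <- table(x$labels[x$cluster])
    cat("  class memberships:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

archetype_classes <- function() {
  c("EXP_HIGH", "STAT_HIGH", "TRANSIENT_UP_EXP", "TRANSIENT_DOWN_EXP",
    "TRANSIENT_UP_TRANSITION", "OTHER")
}

#' Classify a temporal profile into an expression archetype
#'
#' Reduces a (normalized) per-sample profile to its four phase-segment means
#' E, X, T, S (EARLY, EXPONENTIAL, TRANSITION, STATIONARY) and applies
#' margin rules with `delta` in normalized units:
#'
#' * `TRANSIENT_UP_EXP`: `X - E >= delta` and `X - S >= delta`
#' * `TRANSIENT_DOWN_EXP`: `E - X >= delta` and `S - X >= delta`
#' * `TRANSIENT_UP_TRANSITION`: `T - X >= delta` and `T - S >= delta`
#' * `EXP_HIGH`: `X - S >= delta` and `X >= E - delta`
#' * `STAT_HIGH`: `S - X >= delta`
#' * otherwise `OTHER`
#'
#' Rules are tried in that order, transient (pulse) classes before monotone
#' (step) classes, so a pulse is never mislabelled as a step.  All rules use
#' differences only, so adding a constant to the whole profile never changes
#' the label.  A rule needing an empty phase segment is skipped with a
#' message.
#'
#' @param centroid numeric profile over samples (typically a cluster
#'   centroid from [cluster_profiles()]).
#' @param phase_labels character vector of phase labels per entry of
#'   `centroid` (see [sample_phases()]).
#' @param delta classification margin in normalized units (default 0.5).
#' @return a single archetype label.
#' @export
classify_archetype <- function(centroid, phase_labels, delta = 0.5) {
  if (length(centroid) != length(phase_labels))
    stop("centroid and phase_labels lengths differ")
  seg <- vapply(phase_levels(), function(p) {
    v <- centroid[phase_labels == p]
    if (length(v)) mean(v, na.rm = TRUE) else NA_real_
  }, numeric(1))
  E <- seg[["EARLY"]]; X <- seg[["EXPONENTIAL"]]
  Tm <- seg[["TRANSITION"]]; S <- seg[["STATIONARY"]]
  rule <- function(name, needs, test) {
    if (anyNA(needs)) {
      message("archetype rule ", name, " skipped: empty phase segment")
      return(FALSE)
    }
    test
  }
  if (rule("TRANSIENT_UP_EXP", c(E, X, S), isTRUE(X - E >= delta && X - S >= delta)))
    return("TRANSIENT_UP_EXP")
  if (rule("TRANSIENT_DOWN_EXP", c(E, X, S), isTRUE(E - X >= delta && S - X >= delta)))
    return("TRANSIENT_DOWN_EXP")
  if (rule("TRANSIENT_UP_TRANSITION", c(X, Tm, S), isTRUE(Tm - X >= delta && Tm - S >= delta)))
    return("TRANSIENT_UP_TRANSITION")
  if (rule("EXP_HIGH", c(E, X, S), isTRUE(X - S >= delta && X >= E - delta)))
    return("EXP_HIGH")
  if (rule("STAT_HIGH", c(X, S), isTRUE(S - X >= delta)))
    return("STAT_HIGH")
  "OTHER"
}

#' Label every cluster of an archetype result
#'
#' Applies [classify_archetype()] to each cluster centroid.
#'
#' @param result an [cluster_profiles()] result.
#' @param phase_labels per-sample phase labels aligned with the centroid
#'   columns.
#' @param delta classification margin (default 0.5).
#' @return `result` with `labels` (cluster -> archetype) and `delta` filled.
#' @export
classify_archetypes <- function(result, phase_labels, delta = 0.5) {
  stopifnot(inherits(result, "archetype_result"))
  result$labels <- vapply(seq_len(result$K), function(k)
    classify_archetype(result$centroids[k, ], phase_labels, delta),
    character(1))
  names(result$labels) <- as.character(seq_len(result$K))
  result$delta <- delta
  result
}

#' Per-gene archetype labels
#'
#' @param result a labelled [classify_archetypes()] result.
#' @return named character vector gene -> archetype class.
#' @export
gene_archetypes <- function(result) {
  stopifnot(inherits(result, "archetype_result"))
  if (is.null(result$labels)) stop("clusters are not labelled yet")
  out <- result$labels[as.character(result$cluster)]
  names(out) <- names(result$cluster)
  out
}

#' Exact hypergeometric enrichment of a gene set in a category
#'
#' Tests whether a gene set (e.g. genes induced in stationary phase) is
#' over- or under-represented in a category (e.g. plasmid-encoded genes)
#' relative to a gene universe, by the exact hypergeometric tail.  When the
#' observed category fraction `k/n` exceeds the universe fraction `K/N` the
#' upper tail `P(X >= k)` is reported with direction `"over"`; otherwise the
#' lower tail `P(X <= k)` with direction `"under"`.
#'
#' @param set character vector of gene ids (non-empty, within the universe).
#' @param category character vector of category gene ids (within the
#'   universe).
#' @param universe character vector of all gene ids, or an annotation data
#'   frame with a `gene_id` column (see [read_annotation()]).
#' @return An object of class `enrichment_result`: list with `N`, `K`, `n`,
#'   `k`, `p_value`, `direction`.
#' @examples
#' replicon_enrichment(letters[1:10], letters[1:10], letters[1:20])
#' @export
replicon_enrichment <- function(set, category, universe) {
  if (is.data.frame(universe)) universe <- universe$gene_id
  set <- unique(set); category <- unique(category); universe <- unique(universe)
  if (!length(set)) stop("gene set is empty")
  if (length(setdiff(set, universe)))
    stop("gene set contains ids outside the universe")
  if (length(setdiff(category, universe)))
    stop("category contains ids outside the universe")
  N <- length(universe); K <- length(category); n <- length(set)
  k <- length(intersect(set, category))
  if (k / n > K / N) {
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    dir <- "over"
  } else {
    p <- stats::phyper(k, K, N - K, n)
    dir <- "under"
  }
  structure(list(N = N, K = K, n = n, k = k, p_value = p, direction = dir),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Enrichment: %d/%d in set vs %d/%d in universe, %s-represented, p = %.3g\n",
              x$k, x$n, x$K, x$N, x$direction, x$p_value))
  invisible(x)
}
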
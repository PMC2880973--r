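# Domain containers and tab-separated readers/writers.
#
# Single file dialect everywhere: tab separator, UTF-8, mandatory header row,
# "NA" as the missing token, '.' decimal point, full numeric precision on
# write.  All readers validate invariants on construction and fail loudly.

#' Construct a growth curve
#'
#' A growth curve is an OD600 time series for one culture (one strain, one
#' replicate flask).  Time must be strictly increasing and every OD value
#' positive; at least four points are needed before phase annotation is
#' possible.
#'
#' @param strain strain identifier (e.g. `"NRC-1"`).
#' @param replicate replicate identifier (e.g. `"A"`).
#' @param time_h numeric vector of sampling times in hours, strictly
#'   increasing.
#' @param od600 numeric vector of optical densities at 600 nm, all positive,
#'   same length as `time_h`.
#' @return An object of class `growth_curve`: a list with the four fields
#'   above.
#' @examples
#' gc <- growth_curve("NRC-1", "A", 0:5, 0.02 * exp(0.3 * (0:5)))
#' print(gc)
#' @export
growth_curve <- function(strain, replicate, time_h, od600) {
  time_h <- as.numeric(time_h)
  od600 <- as.numeric(od600)
  if (length(time_h) != length(od600))
    stop("time_h and od600 must have the same length")
  if (anyNA(time_h) || anyNA(od600))
    stop("growth curve values must not be missing")
  if (any(diff(time_h) <= 0))
    stop("time_h must be strictly increasing")
  if (any(od600 <= 0))
    stop("all od600 values must be positive")
  structure(
    list(strain = as.character(strain)[1], replicate = as.character(replicate)[1],
         time_h = time_h, od600 = od600),
    class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("Growth curve: strain %s, replicate %s, %d points, %.1f-%.1f h, OD %.3g-%.3g\n",
              x$strain, x$replicate, length(x$time_h),
              min(x$time_h), max(x$time_h), min(x$od600), max(x$od600)))
  invisible(x)
}

#' Read growth curves from CSV
#'
#' Expects columns `strain,replicate,time_h,od600`.  Rows are grouped by
#' (strain, replicate) and each group is validated as a [growth_curve()].
#'
#' @param path path to a CSV file.
#' @return A named list of `growth_curve` objects; names are
#'   `"<strain>.<replicate>"`.
#' @export
read_growth_curves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain", "replicate", "time_h", "od600")
  if (!all(need %in% names(df)))
    stop("growth curve CSV must have columns: ", paste(need, collapse = ", "))
  key <- paste(df$strain, df$replicate, sep = ".")
  out <- lapply(split(df, key), function(d) {
    d <- d[order(d$time_h), ]
    growth_curve(d$strain[1], d$replicate[1], d$time_h, d$od600)
  })
  out[unique(key)]
}

#' Write growth curves to CSV
#'
#' @param curves a `growth_curve` or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_growth_curves <- function(curves, path) {
  if (inherits(curves, "growth_curve")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, function(gc)
    data.frame(strain = gc$strain, replicate = gc$replicate,
               time_h = gc$time_h, od600 = gc$od600)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# canonical sample ordering: within strain by increasing OD600, ties broken
# by replicate then dye orientation
sample_order <- function(samples) {
  order(samples$strain, samples$od600, samples$replicate, samples$dye_flip)
}

#' Construct an expression matrix
#'
#' Holds genes x samples log10 expression ratios against a common reference,
#' an optional aligned matrix of lambda significance values, and per-sample
#' metadata.  Samples are reordered on construction so that within each
#' strain they run along the growth curve in non-decreasing OD600 (ties
#' broken by replicate, then dye orientation) -- the ordering every
#' downstream consecutive-condition operation relies on.
#'
#' Stored ratios are *as measured*: for a dye-flipped sample the test and
#' reference labels are swapped, so its log10 ratio has the opposite sign.
#' Use [oriented_ratios()] to obtain a consistently oriented matrix.
#'
#' @param log10_ratio numeric matrix, genes x samples, with unique non-empty
#'   rownames (gene ids).  Missing values are `NA`, never silent zeros.
#' @param samples data frame with one row per column of `log10_ratio` and
#'   columns `strain`, `replicate`, `dye_flip` (logical), `od600`,
#'   `sample_index` (position along the growth curve).
#' @param lambda optional numeric matrix of the same shape; all values must
#'   be `>= 0` or `NA`.
#' @return An object of class `expression_matrix` with fields `log10_ratio`,
#'   `lambda`, `samples`, `gene_ids`.
#' @export
expression_matrix <- function(log10_ratio, samples, lambda = NULL) {
  log10_ratio <- as.matrix(log10_ratio)
  if (is.null(rownames(log10_ratio)) || any(rownames(log10_ratio) == ""))
    stop("log10_ratio must have gene ids as rownames")
  dup <- rownames(log10_ratio)[duplicated(rownames(log10_ratio))]
  if (length(dup))
    stop("duplicate gene id: ", dup[1])
  samples <- as.data.frame(samples)
  need <- c("strain", "replicate", "dye_flip", "od600", "sample_index")
  if (!all(need %in% names(samples)))
    stop("samples must have columns: ", paste(need, collapse = ", "))
  if (nrow(samples) != ncol(log10_ratio))
    stop("samples has ", nrow(samples), " rows but matrix has ",
         ncol(log10_ratio), " columns")
  samples$dye_flip <- as.logical(samples$dye_flip)
  key <- paste(samples$strain, samples$replicate, samples$sample_index,
               samples$dye_flip)
  if (anyDuplicated(key))
    stop("(strain, replicate, sample_index, dye_flip) must be jointly unique")
  if (!is.null(lambda)) {
    lambda <- as.matrix(lambda)
    if (!identical(dim(lambda), dim(log10_ratio)))
      stop("lambda matrix dimensions must match log10_ratio")
    if (any(lambda < 0, na.rm = TRUE))
      stop("lambda values must be >= 0")
  }
  ord <- sample_order(samples)
  samples <- samples[ord, , drop = FALSE]
  rownames(samples) <- NULL
  log10_ratio <- log10_ratio[, ord, drop = FALSE]
  if (!is.null(lambda)) lambda <- lambda[, ord, drop = FALSE]
  sid <- sprintf("%s.%s.%02d%s", samples$strain, samples$replicate,
                 samples$sample_index, ifelse(samples$dye_flip, ".f", ""))
  colnames(log10_ratio) <- sid
  if (!is.null(lambda)) dimnames(lambda) <- dimnames(log10_ratio)
  samples$sample_id <- sid
  structure(
    list(log10_ratio = log10_ratio, lambda = lambda, samples = samples,
         gene_ids = rownames(log10_ratio)),
    class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d genes x %d samples (%s)%s\n",
              nrow(x$log10_ratio), ncol(x$log10_ratio),
              paste(unique(x$samples$strain), collapse = ", "),
              if (is.null(x$lambda)) "" else ", lambda attached"))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$log10_ratio)

#' Orientation-corrected log10 ratios
#'
#' Returns the log10 ratio matrix with dye-flipped samples sign-inverted, so
#' that every column measures test over reference in the same orientation.
#'
#' @param x an [expression_matrix()].
#' @param logged if `FALSE`, return non-logged ratios `10^r` instead.
#' @return numeric matrix, genes x samples.
#' @export
oriented_ratios <- function(x, logged = TRUE) {
  stopifnot(inherits(x, "expression_matrix"))
  r <- sweep(x$log10_ratio, 2, ifelse(x$samples$dye_flip, -1, 1), `*`)
  if (logged) r else 10^r
}

companion_path <- function(path, tag) {
  sub("(\\.[A-Za-z0-9]+)?$", paste0("_", tag, "\\1"), path, perl = TRUE)
}

read_tsv_matrix <- function(path, what) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop(what, " table must have gene id plus sample columns")
  ids <- df[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate gene id: ", dup[1])
  m <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(m), dim = dim(m)))
  bad <- which(is.na(num) & !is.na(m) & m != "", arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell in %s table at row %d (gene %s), column %s",
                 what, bad[1, 1], ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
  rownames(num) <- ids
  colnames(num) <- colnames(m)
  num
}

#' Read an expression matrix from TSV
#'
#' Reads the ratio table at `path` (first column gene ids, header row naming
#' samples) together with its companion sample-metadata table
#' (`<stem>_samples.tsv`) and, when present, companion lambda table
#' (`<stem>_lambda.tsv`).  All files follow the package dialect (tabs, "NA"
#' missing token, '.' decimal).
#'
#' @param path path to the ratio TSV written by [write_expression_matrix()].
#' @param quiet suppress the one-line parse report.
#' @return A validated [expression_matrix()], samples in canonical order.
#' @export
read_expression_matrix <- function(path, quiet = FALSE) {
  ratios <- read_tsv_matrix(path, "ratio")
  spath <- companion_path(path, "samples")
  if (!file.exists(spath))
    stop("sample metadata table not found: ", spath)
  samples <- utils::read.delim(spath, stringsAsFactors = FALSE)
  samples <- samples[match(colnames(ratios), samples$sample_id), , drop = FALSE]
  if (anyNA(samples$strain))
    stop("sample metadata does not cover all ratio columns")
  lpath <- companion_path(path, "lambda")
  lambda <- NULL
  if (file.exists(lpath)) {
    lambda <- read_tsv_matrix(lpath, "lambda")
    if (!identical(rownames(lambda), rownames(ratios)))
      stop("lambda table gene ids do not match ratio table")
    lambda <- lambda[, colnames(ratios), drop = FALSE]
    if (any(lambda < 0, na.rm = TRUE)) stop("lambda values must be >= 0")
  }
  em <- expression_matrix(ratios, samples, lambda)
  if (!quiet)
    message(sprintf("read %d genes x %d samples from %s (%d missing cells)",
                    nrow(em$log10_ratio), ncol(em$log10_ratio), basename(path),
                    sum(is.na(em$log10_ratio))))
  em
}

write_tsv_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m),
                   format(m, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write an expression matrix to TSV
#'
#' Writes the ratio table to `path`, sample metadata to
#' `<stem>_samples.tsv`, and -- if present -- the lambda table to
#' `<stem>_lambda.tsv`.  Values round-trip bit-for-bit through
#' [read_expression_matrix()] (numbers are written at full double
#' precision).
#'
#' @param x an [expression_matrix()].
#' @param path output path for the ratio table.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  write_tsv_matrix(signif_full(x$log10_ratio), path)
  utils::write.table(x$samples, companion_path(path, "samples"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  if (!is.null(x$lambda))
    write_tsv_matrix(signif_full(x$lambda), companion_path(path, "lambda"))
  invisible(path)
}

# identity; kept as a seam documenting that writers never round
signif_full <- function(m) m

#' Read or write a genome annotation table
#'
#' The annotation maps each gene id to its replicon -- `Chromosome`,
#' `pNRC100` or `pNRC200`.  The two plasmids together carry roughly a fifth
#' of the open reading frames in the genome this models, which is what makes
#' replicon enrichment of growth-phase gene sets informative.
#'
#' @param path TSV path with columns `gene_id`, `replicon`.
#' @return data frame with validated columns `gene_id`, `replicon`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "replicon") %in% names(df)))
    stop("annotation must have columns gene_id, replicon")
  ok <- c("Chromosome", "pNRC100", "pNRC200")
  bad <- setdiff(unique(df$replicon), ok)
  if (length(bad))
    stop("unknown replicon label: ", paste(bad, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene id in annotation")
  df
}

#' @rdname read_annotation
#' @param annotation data frame as returned by [read_annotation()].
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read or write a per-cell morphology table
#'
#' Columns: `cell_id`, `timepoint`, `area` (px^2), `perimeter` (px),
#' `circularity` (in (0, 1]), `major`, `minor` (px), `mean_intensity`.
#'
#' @param path TSV path.
#' @return data frame of per-cell measurements.
#' @export
read_morphology <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "timepoint", "area", "perimeter", "circularity",
            "major", "minor", "mean_intensity")
  if (!all(need %in% names(df)))
    stop("morphology table must have columns: ", paste(need, collapse = ", "))
  if (any(df$circularity <= 0 | df$circularity > 1, na.rm = TRUE))
    stop("circularity must lie in (0, 1]")
  df
}

#' @rdname read_morphology
#' @param cells data frame of per-cell measurements.
#' @export
write_morphology <- function(cells, path) {
  utils::write.table(cells, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read or write a metabolite feature table
#'
#' Long format: one row per (feature, phase, replicate) with columns
#' `feature_id`, `mz`, `rt_min`, `phase` (one of `EARLY`, `EXPONENTIAL`,
#' `STATIONARY`), `replicate`, `abundance` (non-negative).
#'
#' @param path TSV path.
#' @return data frame of metabolite abundances.
#' @export
read_metabolites <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("feature_id", "mz", "rt_min", "phase", "replicate", "abundance")
  if (!all(need %in% names(df)))
    stop("metabolite table must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(df$phase), c("EARLY", "EXPONENTIAL", "STATIONARY"))
  if (length(bad)) stop("unknown phase label: ", paste(bad, collapse = ", "))
  if (any(df$abundance < 0, na.rm = TRUE)) stop("abundances must be >= 0")
  df
}

#' @rdname read_metabolites
#' @param features data frame of metabolite abundances.
#' @export
write_metabolites <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
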
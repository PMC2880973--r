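# Seeded synthetic-data generators with recoverable ground truth for every
# data type the pipeline consumes: growth curves, replicated dye-flip
# expression matrices with planted temporal archetypes, per-cell morphology
# tables, and metabolite feature tables.
#
# Every generator is a pure function of its parameters and seed: the global
# RNG state is saved and restored around each call.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a batch-culture growth curve
#'
#' OD600 follows a logistic trajectory after an optional lag, with an
#' optional delayed secondary rise emulating the late optical-density
#' increase seen when light-scattering gas vesicles accumulate in aging
#' cultures.  Without noise and without a secondary rise the curve is
#' non-decreasing and bounded by `od_max`; the first value is exactly `od0`.
#'
#' @param mu_max maximum specific growth rate, per hour (> 0).
#' @param od0 inoculation OD600 (default 0.02, a standard starting density);
#'   `0 < od0 < od_max`.
#' @param od_max carrying-capacity OD600.
#' @param secondary_rise amplitude (absorbance units) of the late secondary
#'   rise; 0 (default) disables it.
#' @param n_points number of sampling points (>= 4).
#' @param lag_h lag phase duration in hours before logistic growth starts.
#' @param t_max final sampling time (hours); default covers the full curve
#'   plus a stationary tail.
#' @param times explicit sampling times overriding the uniform grid.
#' @param noise_sd lognormal measurement noise sd on OD (0 = noiseless).
#' @param strain,replicate identifiers for the resulting curve.
#' @param seed integer seed (only used when `noise_sd > 0`).
#' @return a [growth_curve()].
#' @examples
#' simulate_growth_curve(0.25, n_points = 7)
#' @export
simulate_growth_curve <- function(mu_max = 0.25, od0 = 0.02, od_max = 1.0,
                                  secondary_rise = 0, n_points = 24L,
                                  lag_h = 0, t_max = NULL, times = NULL,
                                  noise_sd = 0, strain = "NRC-1",
                                  replicate = "A", seed = 1L) {
  if (mu_max <= 0) stop("mu_max must be > 0")
  if (!(od0 > 0 && od0 < od_max)) stop("require 0 < od0 < od_max")
  if (n_points < 4 && is.null(times)) stop("n_points must be >= 4")
  t99 <- log(99 * (od_max - od0) / od0) / mu_max
  if (is.null(t_max)) t_max <- lag_h + 1.4 * t99
  t <- if (is.null(times)) seq(0, t_max, length.out = n_points) else sort(times)
  if (length(t) < 4) stop("n_points must be >= 4")
  # smooth lag: effective growth time ramps in as exp(-t/lag) decays, so OD
  # is strictly increasing from t = 0 (real cultures grow slowly in lag, and
  # downstream OD-based sample ordering must never see exact ties)
  te <- if (lag_h > 0) t - lag_h * (1 - exp(-t / lag_h)) else t
  od <- od_max / (1 + (od_max - od0) / od0 * exp(-mu_max * te))
  od[te == 0] <- od0  # exact at inoculation
  if (secondary_rise > 0) {
    t_sec <- lag_h + 1.15 * t99
    tau <- (max(t) - min(t)) / 30
    s2 <- function(u) 1 / (1 + exp(-(u - t_sec) / tau))
    od <- od + secondary_rise * (s2(t) - s2(t[1]))
  }
  if (noise_sd > 0)
    od <- with_seed(seed, od * exp(stats::rnorm(length(od), 0, noise_sd)))
  growth_curve(strain, replicate, t, od)
}

#' Reference study sampling design
#'
#' A seven-point sampling design over a lagged logistic growth curve, tuned
#' so that all four growth phases are represented and the exponential,
#' transition and stationary segments each contain at least two sampling
#' points -- the layout that makes a four-sample persistence run attainable
#' within one segment when duplicate cultures are interleaved.
#'
#' With the default seven points the layout is one EARLY point (during lag),
#' two EXPONENTIAL, two TRANSITION and two STATIONARY points; other
#' `n_points` fall back to a uniform grid over the same curve.
#'
#' @param n_points number of sampling points (default 7).
#' @param f_exp,f_stat phase thresholds passed to [annotate_phases()].
#' @return a [annotate_phases()] result (`phase_annotation`).
#' @export
study_phases <- function(n_points = 7L, f_exp = 0.5, f_stat = 0.1) {
  gc <- study_growth_curve(n_points)
  annotate_phases(estimate_growth_rates(gc), gc, f_exp = f_exp, f_stat = f_stat)
}

#' @rdname study_phases
#' @param replicate replicate identifier for the returned curve.
#' @export
study_growth_curve <- function(n_points = 7L, replicate = "A") {
  times <- if (n_points == 7L) c(0.5, 5, 21, 31, 39, 42, 59) else NULL
  simulate_growth_curve(mu_max = 0.25, od0 = 0.02, od_max = 1.0,
                        lag_h = 10, n_points = n_points, times = times,
                        replicate = replicate)
}

archetype_template <- function(class, phase_labels, effect) {
  lev <- phase_labels
  val <- switch(class,
    EXP_HIGH = ifelse(lev %in% c("EARLY", "EXPONENTIAL"), effect / 2, -effect / 2),
    STAT_HIGH = ifelse(lev %in% c("EARLY", "EXPONENTIAL"), -effect / 2, effect / 2),
    TRANSIENT_UP_EXP = ifelse(lev == "EXPONENTIAL", effect, 0),
    TRANSIENT_DOWN_EXP = ifelse(lev == "EXPONENTIAL", -effect, 0),
    TRANSIENT_UP_TRANSITION = ifelse(lev == "TRANSITION", effect, 0),
    "NULL" = rep(0, length(lev)),
    stop("unknown archetype class: ", class))
  as.numeric(val)
}

simulated_classes <- function() {
  c("EXP_HIGH", "STAT_HIGH", "TRANSIENT_UP_EXP", "TRANSIENT_DOWN_EXP",
    "TRANSIENT_UP_TRANSITION", "NULL")
}

#' Simulate a replicated dye-flip expression matrix with planted archetypes
#'
#' Generates log10 expression-ratio trajectories for genes planted in the
#' five temporal archetype classes plus null genes.  Class templates are
#' piecewise-constant over the phase segments of `phases`: step classes
#' (`EXP_HIGH`, `STAT_HIGH`) swing `+effect/2` to `-effect/2` between the
#' growing (EARLY+EXPONENTIAL) and late (TRANSITION+STATIONARY) segments;
#' pulse classes deviate by `effect` in their active segment only.  Noise
#' follows the error model of the significance stage,
#' `x = mu (1 + e_mult) + e_add` on the non-logged ratio scale, applied in
#' the oriented frame; dye-flipped samples store the sign-inverted log10
#' ratio.  Lambda values are computed from the simulated replicate structure
#' via [estimate_error_params()] and [compute_lambda()].
#'
#' @param n_per_class named (or positional, in [simulated_classes()] order)
#'   integer vector of gene counts for `EXP_HIGH`, `STAT_HIGH`,
#'   `TRANSIENT_UP_EXP`, `TRANSIENT_DOWN_EXP`, `TRANSIENT_UP_TRANSITION`,
#'   `NULL`; at least one class must be non-zero.
#' @param phases a `phase_annotation` covering the sampled points (default
#'   [study_phases()]).
#' @param effect archetype amplitude in log10 units (> 0 when any non-null
#'   class is planted).
#' @param sigma_add,sigma_mult additive and multiplicative noise scales.
#' @param replicates number of duplicate cultures per timepoint (default 2).
#' @param dye_flip reverse the label orientation of every even replicate
#'   (default `TRUE`), mirroring a dye-flip pair per sampling point.
#' @param strain strain identifier.
#' @param seed integer seed.
#' @param with_lambda compute and attach the lambda matrix (default `TRUE`).
#' @return list with `matrix` (an [expression_matrix()]) and `truth`
#'   (`simulation_truth`: gene -> planted class, the template matrix, noise
#'   parameters, seed).
#' @export
simulate_expression <- function(n_per_class, phases = study_phases(),
                                effect = 1.0, sigma_add = 0.1,
                                sigma_mult = 0.1, replicates = 2L,
                                dye_flip = TRUE, strain = "NRC-1", seed = 1L,
                                with_lambda = TRUE) {
  cls <- simulated_classes()
  if (is.null(names(n_per_class))) {
    if (length(n_per_class) != length(cls))
      stop("n_per_class must be named or have length ", length(cls))
    names(n_per_class) <- cls
  }
  n_per_class <- n_per_class[cls]
  n_per_class[is.na(n_per_class)] <- 0
  names(n_per_class) <- cls
  if (sum(n_per_class) == 0) stop("zero genes in all classes")
  if (effect <= 0 && sum(n_per_class[cls != "NULL"]) > 0)
    stop("effect must be > 0 when non-null classes are planted")
  stopifnot(inherits(phases, "phase_annotation"))
  ntp <- length(phases$labels)
  G <- sum(n_per_class)
  gene_labels <- rep(cls, n_per_class)
  gene_ids <- sprintf("VNGS%04d", seq_len(G))
  names(gene_labels) <- gene_ids
  template <- t(vapply(gene_labels, archetype_template,
                       numeric(ntp), phase_labels = phases$labels,
                       effect = effect))
  rownames(template) <- gene_ids
  mu <- 10^template   # true oriented non-logged ratio per gene x timepoint
  samples <- expand.grid(replicate = LETTERS[seq_len(replicates)],
                         sample_index = seq_len(ntp),
                         stringsAsFactors = FALSE)
  samples$strain <- strain
  samples$od600 <- phases$od600[samples$sample_index]
  samples$dye_flip <- dye_flip &
    (match(samples$replicate, LETTERS) %% 2 == 0)
  obs <- with_seed(seed, {
    o <- matrix(NA_real_, G, nrow(samples))
    for (j in seq_len(nrow(samples))) {
      m <- mu[, samples$sample_index[j]]
      x <- m * (1 + stats::rnorm(G, 0, sigma_mult)) + stats::rnorm(G, 0, sigma_add)
      bad <- which(x <= 0)
      while (length(bad)) {  # resample non-positive ratios, keep model well-specified
        x[bad] <- m[bad] * (1 + stats::rnorm(length(bad), 0, sigma_mult)) +
          stats::rnorm(length(bad), 0, sigma_add)
        bad <- bad[x[bad] <= 0]
      }
      o[, j] <- x
    }
    o
  })
  lr <- log10(obs) * matrix(ifelse(samples$dye_flip, -1, 1), G,
                            nrow(samples), byrow = TRUE)
  rownames(lr) <- gene_ids
  em <- expression_matrix(lr, samples)
  if (with_lambda) em <- compute_lambda(em)
  truth <- structure(
    list(gene_labels = gene_labels, template = template,
         n_per_class = n_per_class, effect = effect,
         sigma_add = sigma_add, sigma_mult = sigma_mult,
         replicates = replicates, seed = seed),
    class = "simulation_truth")
  list(matrix = em, truth = truth)
}

#' Simulate a per-cell morphology table from a mixture trajectory
#'
#' Draws per-cell circularities at each timepoint from a two-component
#' Gaussian mixture truncated to (0, 1] by resampling (not clipping, so the
#' mixture family stays well-specified), and fills the remaining
#' measurement columns consistently: cell area is lognormal, the perimeter
#' reproduces the drawn circularity exactly, and low circularity maps to a
#' high aspect ratio (elongated rods).
#'
#' @param trajectory data frame with one row per timepoint and columns
#'   `w2` (weight of the high-circularity component, in \[0, 1\]), `mu1`,
#'   `mu2` (component means, in (0, 1], `mu1 <= mu2`), `sigma1`, `sigma2`
#'   (> 0); optional `timepoint` and `intensity` (per-timepoint mean
#'   intensity, default 100) columns.
#' @param n_cells cells per timepoint: a scalar or one count per row.
#' @param seed integer seed.
#' @return list with `cells` (morphology data frame, see
#'   [read_morphology()]) and `truth` (`simulation_truth` with the planted
#'   trajectory, per-cell component assignments and seed).
#' @export
simulate_morphology <- function(trajectory, n_cells = 500L, seed = 1L) {
  tr <- as.data.frame(trajectory)
  need <- c("w2", "mu1", "mu2", "sigma1", "sigma2")
  if (!all(need %in% names(tr)))
    stop("trajectory must have columns: ", paste(need, collapse = ", "))
  if (any(tr$w2 < 0 | tr$w2 > 1)) stop("w2 must lie in [0, 1]")
  if (any(tr$mu1 <= 0 | tr$mu1 > 1 | tr$mu2 <= 0 | tr$mu2 > 1))
    stop("component means must lie in (0, 1]")
  if (any(tr$sigma1 <= 0 | tr$sigma2 <= 0)) stop("component sds must be > 0")
  if (is.null(tr$timepoint)) tr$timepoint <- seq_len(nrow(tr))
  if (is.null(tr$intensity)) tr$intensity <- 100
  n_cells <- rep_len(n_cells, nrow(tr))
  if (any(n_cells < 1)) stop("n_cells must be >= 1")
  res <- with_seed(seed, {
    rows <- list(); comps <- list()
    for (i in seq_len(nrow(tr))) {
      n <- n_cells[i]
      comp <- stats::rbinom(n, 1, tr$w2[i]) + 1L
      m <- c(tr$mu1[i], tr$mu2[i])[comp]
      s <- c(tr$sigma1[i], tr$sigma2[i])[comp]
      circ <- stats::rnorm(n, m, s)
      bad <- which(circ <= 0 | circ > 1)
      while (length(bad)) {
        circ[bad] <- stats::rnorm(length(bad), m[bad], s[bad])
        bad <- bad[circ[bad] <= 0 | circ[bad] > 1]
      }
      area <- stats::rlnorm(n, log(600), 0.25)
      per <- sqrt(4 * pi * area / circ)
      ar <- 1 / circ   # low circularity => elongated
      minor <- sqrt(4 * area / (pi * ar))
      rows[[i]] <- data.frame(
        cell_id = sprintf("t%02d_c%04d", tr$timepoint[i], seq_len(n)),
        timepoint = tr$timepoint[i], area = area, perimeter = per,
        circularity = circ, major = ar * minor, minor = minor,
        mean_intensity = stats::rnorm(n, tr$intensity[i], 5),
        stringsAsFactors = FALSE)
      comps[[i]] <- comp
    }
    list(cells = do.call(rbind, rows), comp = unlist(comps))
  })
  truth <- structure(
    list(trajectory = tr, component = res$comp, n_cells = n_cells,
         seed = seed),
    class = "simulation_truth")
  list(cells = res$cells, truth = truth)
}

#' Simulate a metabolite feature table with planted concordant features
#'
#' Background features are flat across the three phases with multiplicative
#' noise; the first `n_concordant` features follow `gene_group_profile`
#' rescaled in log space so that the early-to-stationary ratio equals
#' `fold`.
#'
#' @param n_features total feature count.
#' @param n_concordant number of planted concordant features
#'   (`<= n_features`).
#' @param gene_group_profile length-3 relative abundance pattern over
#'   (EARLY, EXPONENTIAL, STATIONARY).  When its first and last entries
#'   differ the pattern is rescaled in log space to the requested `fold`;
#'   when they are equal (a symmetric pulse) the shape is used as given and
#'   `fold` is ignored with a message.
#' @param fold planted early-to-stationary fold change (>= 1).
#' @param noise_cv replicate coefficient of variation (0 = noiseless).
#' @param replicates replicates per phase (>= 2).
#' @param seed integer seed.
#' @return list with `features` (long-format table, see
#'   [read_metabolites()]) and `truth` (`simulation_truth` with planted
#'   feature ids, phase means and seed).
#' @export
simulate_metabolites <- function(n_features = 150L, n_concordant = 10L,
                                 gene_group_profile = c(1, 0.4, 4), fold = 4,
                                 noise_cv = 0.1, replicates = 3L, seed = 1L) {
  if (replicates < 2) stop("replicates must be >= 2")
  if (fold < 1) stop("fold must be >= 1")
  if (n_concordant > n_features) stop("n_concordant exceeds n_features")
  prof <- as.numeric(gene_group_profile)
  if (length(prof) != 3 || any(prof <= 0))
    stop("gene_group_profile must be 3 positive values")
  if (prof[3] == prof[1]) {
    # symmetric pattern (e.g. high-low-high): the early/stationary fold is
    # undefined, so the profile shape is used as given
    if (fold > 1)
      message("profile has equal EARLY and STATIONARY levels; fold ignored")
    scaled <- prof / prof[1]
  } else {
    scaled <- (prof / prof[1])^(log(fold) / log(prof[3] / prof[1]))
  }
  ph <- metabolite_phases()
  res <- with_seed(seed, {
    base <- stats::rlnorm(n_features, log(1e4), 0.5)
    mz <- stats::runif(n_features, 85, 1200)
    rt <- stats::runif(n_features, 1, 40)
    rows <- list()
    for (i in seq_len(n_features)) {
      means <- if (i <= n_concordant) base[i] * scaled else rep(base[i], 3)
      for (p in 1:3) for (r in seq_len(replicates)) {
        ab <- means[p] * (1 + stats::rnorm(1, 0, noise_cv))
        rows[[length(rows) + 1L]] <- data.frame(
          feature_id = sprintf("M%04d", i), mz = mz[i], rt_min = rt[i],
          phase = ph[p], replicate = r, abundance = max(ab, 0),
          stringsAsFactors = FALSE)
      }
    }
    list(tab = do.call(rbind, rows), base = base)
  })
  concordant <- if (n_concordant > 0) sprintf("M%04d", seq_len(n_concordant))
                else character(0)
  truth <- structure(
    list(concordant = concordant, profile = scaled, fold = fold,
         noise_cv = noise_cv, seed = seed),
    class = "simulation_truth")
  list(features = res$tab, truth = truth)
}
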
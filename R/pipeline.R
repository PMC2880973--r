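# End-to-end pipeline driver and summary-report helpers.

#' Integer percentage for summary reports
#'
#' The convention used everywhere a stage report prints a percentage:
#' `round(100 * count / total)` to the nearest integer.  With it, 1223 of
#' 1518 filtered genes in the two dominant classes reads as 81%, 1518 of
#' 2400 genes as 63%, and 15 of 451 as 3%.
#'
#' @param count numerator count.
#' @param total denominator count (> 0).
#' @return integer percentage.
#' @examples
#' report_percent(451 + 772, 1518)  # 81
#' @export
report_percent <- function(count, total) {
  if (any(total <= 0)) stop("total must be positive")
  as.integer(round(100 * count / total))
}

#' Default pipeline configuration
#'
#' Flat named list of every tunable the pipeline uses; all thresholds,
#' simulation settings and phase fractions live here, never hard-coded in
#' the stages.  Any entry can be overridden via `...`.
#'
#' @param ... overrides, e.g. `phasewave_config(lambda0 = 10)`.
#' @return named list of configuration values.
#' @export
phasewave_config <- function(...) {
  cfg <- list(
    # simulation design
    n_timepoints = 7L, replicates = 2L, dye_flip = TRUE,
    # class sizes mirror the reported memberships of the five temporal
    # patterns in a ~2400-gene genome: 451 exponential-high, 772
    # stationary-high, 10 / 4 / 18 genes in the three transient patterns,
    # the remainder null
    n_per_class = c(EXP_HIGH = 451, STAT_HIGH = 772, TRANSIENT_UP_EXP = 10,
                    TRANSIENT_DOWN_EXP = 4, TRANSIENT_UP_TRANSITION = 18,
                    "NULL" = 1145),
    effect = 1.0, sigma_add = 0.1, sigma_mult = 0.1,
    plasmid_fraction = 0.2,
    # growth / phases
    f_exp = 0.5, f_stat = 0.1,
    # significance filter
    lambda0 = 15, run_length = 4L,
    sweep_lambda0 = c(15, 12, 10, 7), sweep_k = c(4, 3, 2, 1),
    # clustering / archetypes
    K = 10L, n_restarts = 25L, delta = 0.5,
    # strain comparison
    n_perm = 1000L, alpha = 0.01, max_false_prop = 0.01,
    endpoint_alpha = 0.05, endpoint_fdr = 0.05,
    # morphology
    n_cells = 500L, min_cells = 50L,
    # metabolites
    n_features = 150L, n_concordant = 10L, metab_fold = 4,
    metab_noise_cv = 0.1, metab_replicates = 3L,
    p_metab = 0.001, min_fold = 3)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

write_stage <- function(df, out_dir, name) {
  utils::write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

#' Run the full growth-curve analysis pipeline on simulated data
#'
#' Executes every stage in order on a synthetic study generated from
#' `config` and `seed`: growth simulation and phase annotation, lambda
#' persistence filtering and the threshold sweep, row normalization,
#' K-means clustering and archetype classification, a second-strain
#' comparison by permutation t-test, replicon enrichment of the
#' stationary-high set, the morphology mixture trajectory, and metabolite
#' filtering plus transcript concordance.  All stage outputs and a
#' machine-readable `summary.tsv` are written to `out_dir`.  Identical
#' `config` and `seed` give identical outputs.
#'
#' @param config a [phasewave_config()] list.
#' @param seed integer master seed; stage seeds are derived from it.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the stage results and the named `summary`
#'   vector.
#' @export
run_pipeline <- function(config = phasewave_config(), seed = 1L,
                         out_dir = tempfile("phasewave")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  phases <- stage("phases",
    study_phases(config$n_timepoints, config$f_exp, config$f_stat))
  curve <- stage("phases", study_growth_curve(config$n_timepoints))
  write_stage(data.frame(time_h = phases$time_h, od600 = phases$od600,
                         phase = phases$labels), out_dir, "phases.tsv")

  sim <- stage("simulate", simulate_expression(
    config$n_per_class, phases, effect = config$effect,
    sigma_add = config$sigma_add, sigma_mult = config$sigma_mult,
    replicates = config$replicates, dye_flip = config$dye_flip,
    seed = seed))
  em <- sim$matrix
  write_expression_matrix(em, file.path(out_dir, "expression.tsv"))

  sig <- stage("lambda_filter", persistent_significant_set(
    em, config$lambda0, config$run_length))
  sweep <- stage("lambda_filter", threshold_sweep(
    em, config$sweep_lambda0, config$sweep_k))
  write_stage(as.data.frame(sweep), out_dir, "sweep.tsv")
  writeLines(sig, file.path(out_dir, "significant_genes.txt"))

  arch <- stage("cluster", {
    norm <- row_normalize(em)[sig, , drop = FALSE]
    res <- cluster_profiles(norm, K = min(config$K, length(sig)),
                            seed = seed, n_restarts = config$n_restarts)
    classify_archetypes(res, sample_phases(em, phases), config$delta)
  })
  classes <- gene_archetypes(arch)
  write_stage(data.frame(gene_id = names(classes), cluster = arch$cluster,
                         archetype = unname(classes)),
              out_dir, "archetypes.tsv")

  compare <- stage("compare", {
    simB <- simulate_expression(config$n_per_class, phases,
                                effect = config$effect,
                                sigma_add = config$sigma_add,
                                sigma_mult = config$sigma_mult,
                                replicates = config$replicates,
                                dye_flip = config$dye_flip,
                                strain = "MUT", seed = seed + 1000L,
                                with_lambda = FALSE)
    permutation_differential(oriented_ratios(em),
                             oriented_ratios(simB$matrix),
                             n_perm = config$n_perm, alpha = config$alpha,
                             max_false_prop = config$max_false_prop,
                             seed = seed)
  })
  write_stage(as.data.frame(compare), out_dir, "strain_comparison.tsv")
  endpoint <- stage("compare", endpoint_change_test(
    em, config$endpoint_alpha, config$endpoint_fdr))
  write_stage(endpoint, out_dir, "endpoint_test.tsv")

  enrich <- stage("enrich", {
    anno <- with_seed(seed + 2000L, data.frame(
      gene_id = em$gene_ids,
      replicon = sample(c("Chromosome", "pNRC100", "pNRC200"),
                        length(em$gene_ids), replace = TRUE,
                        prob = c(1 - config$plasmid_fraction,
                                 config$plasmid_fraction / 2,
                                 config$plasmid_fraction / 2)),
      stringsAsFactors = FALSE))
    write_annotation(anno, file.path(out_dir, "annotation.tsv"))
    stat_high <- names(classes)[classes == "STAT_HIGH"]
    plasmid <- anno$gene_id[anno$replicon != "Chromosome"]
    if (length(stat_high))
      replicon_enrichment(stat_high, plasmid, anno)
    else NULL
  })

  morph <- stage("morph", {
    tr <- data.frame(w2 = c(0.15, 0.1, 0.1, 0.4, 0.4, 0.2, 0.15),
                     mu1 = c(0.4, 0.32, 0.3, 0.35, 0.35, 0.35, 0.4),
                     mu2 = c(0.8, 0.75, 0.72, 0.88, 0.88, 0.8, 0.78),
                     sigma1 = 0.08, sigma2 = 0.05)[seq_len(config$n_timepoints), ]
    simc <- simulate_morphology(tr, n_cells = config$n_cells,
                                seed = seed + 3000L)
    write_morphology(simc$cells, file.path(out_dir, "cells.tsv"))
    population_trajectory(simc$cells, curve, min_n = config$min_cells)
  })
  write_stage(morph$table, out_dir, "morphology_trajectory.tsv")

  metab <- stage("metab", {
    simm <- simulate_metabolites(config$n_features, config$n_concordant,
                                 fold = config$metab_fold,
                                 noise_cv = config$metab_noise_cv,
                                 replicates = config$metab_replicates,
                                 seed = seed + 4000L)
    write_metabolites(simm$features, file.path(out_dir, "metabolites.tsv"))
    filtered <- filter_significant_features(simm$features, config$p_metab,
                                            config$min_fold)
    write_stage(filtered, out_dir, "metabolite_filter.tsv")
    list(filtered = filtered, truth = simm$truth)
  })

  cls_counts <- table(factor(classes, levels = archetype_classes()))
  n_genes <- length(em$gene_ids)
  dominant <- sum(cls_counts[c("EXP_HIGH", "STAT_HIGH")])
  summary <- c(
    n_genes = n_genes,
    n_significant = length(sig),
    pct_significant = report_percent(length(sig), n_genes),
    stats::setNames(as.integer(cls_counts),
                    paste0("n_", tolower(names(cls_counts)))),
    pct_dominant = if (length(sig)) report_percent(dominant, length(sig)) else 0L,
    n_strain_different = sum(compare$significant),
    n_endpoint_flagged = sum(endpoint$flag),
    enrichment_p = if (is.null(enrich)) NA_real_ else enrich$p_value,
    n_metab_retained = sum(metab$filtered$retained),
    peak_w2 = max(morph$table$w2))
  sm <- data.frame(key = names(summary), value = unname(summary))
  write_stage(sm, out_dir, "summary.tsv")
  invisible(list(phases = phases, expression = em, truth = sim$truth,
                 significant = sig, sweep = sweep, archetypes = arch,
                 comparison = compare, endpoint = endpoint,
                 enrichment = enrich, morphology = morph,
                 metabolites = metab, summary = summary,
                 out_dir = out_dir))
}
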
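# Shared fixture builders: everything is generated in code at test time.

# minimal expression matrix: one strain, one culture, no dye flips,
# log10 ratios supplied column by column in growth order
tiny_expression_matrix <- function(values, gene_ids = NULL, strain = "NRC-1",
                                   lambda = NULL) {
  m <- as.matrix(values)
  if (is.null(gene_ids)) gene_ids <- sprintf("VNG%04dG", seq_len(nrow(m)))
  rownames(m) <- gene_ids
  samples <- data.frame(strain = strain, replicate = "A",
                        dye_flip = FALSE, od600 = seq_len(ncol(m)) * 0.1,
                        sample_index = seq_len(ncol(m)))
  expression_matrix(m, samples, lambda)
}

# rasterized shapes for shape-metric oracles
raster_disc <- function(r, pad = 3L) {
  n <- 2L * r + 2L * pad
  ctr <- (n + 1) / 2
  xy <- expand.grid(i = seq_len(n), j = seq_len(n))
  matrix(as.integer((xy$i - ctr)^2 + (xy$j - ctr)^2 <= r^2), n, n)
}

raster_rect <- function(w, h, pad = 3L) {
  m <- matrix(0L, h + 2L * pad, w + 2L * pad)
  m[(pad + 1):(pad + h), (pad + 1):(pad + w)] <- 1L
  m
}

# independent run-scan oracle for the persistence filter
run_oracle <- function(lam_row, lambda0, k) {
  n <- length(lam_row)
  if (k > n) return(FALSE)
  for (i in seq_len(n - k + 1)) {
    w <- lam_row[i:(i + k - 1)]
    if (!anyNA(w) && all(w > lambda0)) return(TRUE)
  }
  FALSE
}

# archetype recovery of planted non-null labels through the full path:
# lambda persistence filter -> row normalization -> K-means -> rule labels
archetype_recovery <- function(sim, phases, K = 10, seed = 1,
                               lambda0 = 15, k = 4, delta = 0.5) {
  sig <- persistent_significant_set(sim$matrix, lambda0, k)
  labs <- sim$truth$gene_labels
  nn <- names(labs)[labs != "NULL"]
  if (!length(sig)) return(0)
  norm <- row_normalize(sim$matrix)[sig, , drop = FALSE]
  res <- cluster_profiles(norm, K = min(K, length(sig)), seed = seed)
  res <- classify_archetypes(res, sample_phases(sim$matrix, phases), delta)
  ga <- gene_archetypes(res)
  common <- intersect(nn, names(ga))
  sum(ga[common] == labs[common]) / length(nn)
}
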
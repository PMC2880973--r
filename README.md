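# phasewave

Systems analysis of microbial batch growth curves in R.

A single batch culture is a surprisingly rich experiment: as cells consume
nutrients and oxygen they drive their own environment through a sequence of
states — lag, rapid exponential growth, a transition, and stationary phase —
and in organisms like the halophilic archaeon *Halobacterium salinarum*
NRC-1 this self-imposed perturbation re-regulates the majority of the
genome. `phasewave` packages the analysis toolchain such a study needs, for
anyone who profiles transcripts, metabolites or cell morphology along an
OD600 growth curve:

* **Growth phases** — specific growth rate `mu(t) = d ln(OD)/dt` by finite
  differences, replicate agreement as RMSD over matched sampling points, and
  a four-phase partition (EARLY / EXPONENTIAL / TRANSITION / STATIONARY)
  from configurable thresholds `mu >= f_exp * mu_max` and
  `mu <= f_stat * mu_max`.
* **Significance of expression change** — per-gene, per-condition
  likelihood-ratio statistics `lambda` for two-colour log10 ratios under a
  Gaussian additive + multiplicative error model
  `x = mu (1 + e_mult) + e_add`, so `Var(x | mu) = sigma_add^2 +
  mu^2 sigma_mult^2`.  Testing the unit true ratio gives the closed form
  `lambda = n (xbar - 1)^2 / sigma^2(xbar)`, approximately chi-square(1)
  under the null.  A gene is called significant when `lambda > lambda0`
  (default 15) holds over at least `k` (default 4) consecutive
  growth-ordered samples, duplicate dye-flip cultures included; threshold
  sweep tables report how the count grows as either knob is relaxed.
* **Temporal archetypes** — row-normalized profiles, seeded k-means++ /
  Lloyd clustering with restarts, and margin rules that classify each
  cluster centroid into one of five temporal classes (exponential-high,
  stationary-high, transient up/down in exponential, transient up at the
  transition) or OTHER.
* **Strain comparison** — per-gene permutation t-tests (full enumeration on
  small designs) with SAM-style false-significant-proportion control, plus
  fold change defined as the ratio of mean non-logged ratios over the last
  four vs first four samples of the growth curve, and a first-four/last-four
  endpoint t-test with Benjamini–Hochberg FDR control.
* **Replicon enrichment** — exact hypergeometric tails for over- or
  under-representation of, e.g., plasmid-encoded genes (pNRC100/pNRC200) in
  a phase-associated gene set.
* **Cell morphology** — circularity `C = min(1, 4 pi A / P^2)` from binary
  masks with a corner-corrected chain-length perimeter, hand-written EM for
  a two-component Gaussian mixture separating rod (low C) from spherical
  (high C) cells, per-timepoint population trajectories, and the
  median-intensity gas-vesicle index.
* **Metabolite concordance** — the p < 0.001 and >= 3-fold
  early-vs-stationary filters for metabolite features, and Pearson
  concordance between a metabolite's standardized three-phase profile and a
  gene group's phase-averaged expression profile.
* **Synthetic data** — seeded generators with recoverable ground truth for
  every data type (growth curves, dye-flip expression matrices with planted
  archetypes, per-cell morphology tables, metabolite features), so every
  stage is testable end to end without the original microarray scans.

## Worked example

Simulate the reference study design — 2400 genes, seven sampling points
across all four phases, duplicate cultures with one dye-flip pair per point
— then filter, cluster, and classify:

```r
library(phasewave)

ph <- study_phases()
ph
#> Phase annotation (f_exp = 0.5 , f_stat = 0.1 ): EARLY=1 EXPONENTIAL=2 TRANSITION=2 STATIONARY=2

sim <- simulate_expression(
  c(EXP_HIGH = 451, STAT_HIGH = 772, TRANSIENT_UP_EXP = 10,
    TRANSIENT_DOWN_EXP = 4, TRANSIENT_UP_TRANSITION = 18, "NULL" = 1145),
  ph, seed = 1)
sim$matrix
#> Expression matrix: 2400 genes x 14 samples (NRC-1), lambda attached

sig <- persistent_significant_set(sim$matrix, lambda0 = 15, k = 4)
length(sig)
#> [1] 1255

arch <- cluster_profiles(row_normalize(sim$matrix)[sig, ], K = 10, seed = 1)
arch <- classify_archetypes(arch, sample_phases(sim$matrix, ph))
arch
#> Archetype result: 1255 genes in K = 10 clusters (WSS 626)
#>   class memberships: EXP_HIGH=451 STAT_HIGH=776 TRANSIENT_UP_EXP=10 TRANSIENT_UP_TRANSITION=18
```

The persistence filter recovers exactly the 1255 planted non-null genes
(52% of the simulated genome) with no false calls, and the archetype rules
re-identify the planted classes; the four-gene transient-down class is too
small to claim its own cluster at K = 10 and is absorbed by the large
stationary-high cluster — a real resolution limit of class-level K-means,
not a bug.

Morphology follows the same pattern: plant a mixture trajectory, fit it
back per timepoint:

```r
tr <- data.frame(w2 = c(0.15, 0.1, 0.1, 0.4, 0.4, 0.2, 0.15),
                 mu1 = c(0.4, 0.32, 0.3, 0.35, 0.35, 0.35, 0.4),
                 mu2 = c(0.8, 0.75, 0.72, 0.88, 0.88, 0.8, 0.78),
                 sigma1 = 0.08, sigma2 = 0.05)
cells <- simulate_morphology(tr, n_cells = 500, seed = 1)$cells
population_trajectory(cells, study_growth_curve())$table[, c("timepoint", "od600", "w2", "mu2")]
#>  timepoint      od600        w2       mu2
#>          1 0.02006033 0.1510458 0.7923393
#>          2 0.02594488 0.1004463 0.7411632
#>          3 0.30244557 0.1039731 0.7250938
#>          4 0.81317936 0.4139946 0.8785763
#>          5 0.96797795 0.3879950 0.8797704
#>          6 0.98441393 0.1939941 0.7997197
#>          7 0.99976718 0.1347491 0.7731856
```

The fitted fraction of spherical cells `w2(t)` reproduces the planted pulse
at timepoints 4–5 — the rod-to-coccus shift during the growth "flattening".

`run_pipeline(phasewave_config(), seed = 1, out_dir = "out")` chains every
stage (phases → lambda filter → clustering/archetypes → strain comparison →
enrichment → morphology → metabolites) and writes per-stage TSVs plus a
machine-readable `summary.tsv`; identical config and seed give
byte-identical outputs.

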
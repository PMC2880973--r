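---
title: "Growth-phase resolved analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-phase resolved analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasewave)
```

`phasewave` analyses what happens to a microbial population as a single
batch culture drives itself from inoculation to stationary phase.  This
vignette is the package's own account of the statistical machinery: the
models and their assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic-data generators do and do not
emulate, and the places where a design had to be chosen among reasonable
alternatives.

## Growth curves and phase annotation

The specific growth rate is estimated as `mu(t) = d ln(OD600)/dt` by
central finite differences on log OD (one-sided at the ends), which is
exact on exponential segments.  No smoothing is applied by default; an
odd-width moving average on log OD is available (`smooth_window`) for noisy
curves.  Replicate flask agreement is the root-mean-square distance of OD
at matched sampling times; matching is exact (within a small time
tolerance) and never interpolated, because replicate cultures in this kind
of design share a sampling schedule.

The growth literature names the phases of batch growth but gives no
operational boundaries, so the partition here is an explicit convention:
the EXPONENTIAL block is the contiguous run of points around the `mu`
maximum with `mu >= f_exp * mu_max`; everything before it is EARLY; the
trailing run with `mu <= f_stat * mu_max` is STATIONARY; whatever lies
between is TRANSITION.  Defaults `f_exp = 0.5` and `f_stat = 0.1`
(fractions of `mu_max`, dimensionless) make the partition monotone in both
knobs — raising `f_exp` can only shrink the exponential block — and both
values are recorded in every `phase_annotation` so downstream outputs carry
their provenance.  TRANSITION is kept as a first-class label because
transiently induced genes at the exponential-to-stationary handover are one
of the signals this analysis exists to find.

## The lambda statistic and the persistence filter

Two-colour ratio data carry noise with both an intensity-independent and a
proportional component.  The error model is

    x = mu * (1 + e_mult) + e_add,   e_add ~ N(0, sigma_add^2),  e_mult ~ N(0, sigma_mult^2)

for an observed (oriented, non-logged) ratio `x` with true ratio `mu`, so
`Var(x | mu) = sigma_add^2 + mu^2 sigma_mult^2`.  The original maximum-
likelihood significance machinery for this kind of data was never published
with its parametric form, so this Gaussian two-component family — the
standard form such error models take — is a documented package choice, and
the package validates it by its *calibration* rather than by matching any
historical statistic values.

`estimate_error_params()` fits `(sigma_add, sigma_mult)` by maximum
likelihood across thousands of genes, profiling out each gene's true ratio
with its replicate mean and maximizing the chi-square likelihood of the
per-gene residual sums of squares.  At 5000 genes with 4 replicates both
parameters are recovered well within ±20% (the acceptance suite checks
this), and purely additive data drives `sigma_mult` to its floor.

`lambda_statistic()` is the 1-degree-of-freedom likelihood-ratio statistic
for H0: `mu = 1` (equal abundance in both channels) with the variance
profiled at the gene's observed mean level:

    lambda = n * (xbar - 1)^2 / (sigma_add^2 + xbar^2 * sigma_mult^2)

It is exactly zero when the replicate ratios average to one, strictly
increasing in `|xbar - 1|` at fixed noise, and approximately chi-square(1)
under the null: on 10,000 simulated null genes the rejection rate at the
chi-square 95th percentile lands inside 0.05 ± 0.01.  Dye-flipped samples
are sign-corrected before any statistic is computed, so a global swap of
the two channels (with flags toggled) leaves every lambda unchanged.

A gene is *persistently* significant when some run of at least `k = 4`
consecutive growth-ordered samples has `lambda` strictly above
`lambda0 = 15`.  Three conventions matter and are all deliberate:

* Samples are ordered within a strain by increasing OD600, duplicate
  cultures interleaved — so a run of four can span two timepoints times two
  replicate cultures, the most literal reading of "consecutive data points
  including duplicate samples".
* The threshold is strict (`> 15`, not `>=`).
* A missing lambda breaks a run rather than being skipped — conservative.

Runs are scanned within each strain separately and the results unioned;
whether the original analysis ordered strains jointly is unknowable from
the outside, and per-strain scanning is the only variant that cannot
manufacture a run across biologically unrelated columns.
`threshold_sweep()` tabulates the retained-gene count over grids of
`lambda0` and `k` and verifies the two monotonicity invariants (counts can
only grow as either knob is relaxed) on every call.

## Temporal archetypes

Filtered genes are row-normalized (mean 0, population-sd 1 per gene, over
non-missing entries) so clustering sees shape, not amplitude.  K-means uses
k-means++-style farthest-point seeding from a seeded generator, Lloyd
iterations, and 25 restarts keeping the lowest within-cluster sum of
squares; everything is deterministic given the seed.  `K = 10` by default:
the biology defines five pattern classes, but letting K exceed the class
count lets heterogeneous big classes occupy several clusters before the
rule-based labelling merges them.  Missing values are imputed at 0 — the
row mean after normalization — which is neutral for squared-error
clustering.

Each centroid is reduced to its phase-segment means (E, X, T, S) and
labelled by margin rules with `delta = 0.5` normalized units: pulse rules
(transient up/down in exponential, transient up at transition) are checked
before step rules (exponential-high, stationary-high), so a pulse is never
mislabelled as a step; all rules use differences only, making the labels
invariant to profile shifts; a rule whose required phase segment is empty
is skipped with a message.  `delta` is half a standard deviation of a
normalized profile — small enough to catch genuine contrasts, large enough
that flat-ish centroids fall through to OTHER.

A four-gene planted class can fail to claim its own cluster at `K = 10`
and be absorbed by a large neighbour; the package reports what the
clustering actually resolves rather than forcing one cluster per class.

## Strain comparison

Per-gene two-sample t statistics (Welch by default; pooled variance by
switch) are computed on logged ratios, with p-values by permutation of the
sample labels: full enumeration whenever the number of distinct
arrangements fits the permutation budget (p is then an exact fraction with
the identity arrangement always counted), sampled otherwise (with the
`+1/(B+1)` convention so p is never zero).  The false-significant-
proportion step mirrors SAM: candidate rejection sets are nested by `|t|`
among genes passing `alpha`; the median over permutations of the number of
permuted statistics in the region estimates the expected null count; the
largest set whose estimated false proportion stays within `max_false_prop`
(default 0.01, matching the overall `alpha = 0.01`) is declared
significant.  The historical implementation of this procedure is not
bit-reproducible, so the package asserts its statistical behaviour instead:
valid p-values under exchangeable nulls and type-I error at the nominal
rate within Monte-Carlo error.

Fold change is the ratio of the mean *non-logged* ratio over the last four
growth-ordered samples to the first four (replicates included), reported on
the non-logged scale; the endpoint change test compares the same two
windows per gene with Benjamini–Hochberg FDR control at 0.05.

## Replicon enrichment

Whether a phase-associated gene set over-represents plasmid-encoded genes
is tested by the exact hypergeometric tail — upper tail when the observed
category fraction exceeds the universe fraction, lower tail otherwise, with
the direction reported.  The counts (N, K, n, k) are always explicit
arguments: the published gene totals for this genome are internally
inconsistent at the tens-of-genes level, so the package never guesses a
denominator.  Agreement with brute-force subset enumeration is verified for
every universe size up to 15.

## Morphology mixtures

Circularity `C = min(1, 4 pi A / P^2)` uses pixel-count area and a
corner-corrected chain-length perimeter (axis steps 1, diagonal steps
sqrt 2 along the traced 8-connected boundary); the correction is what keeps
a rasterized disc near `C = 1` where a naive crack count overshoots the
perimeter by ~27%.  Axis lengths come from second central moments (the
ellipse-of-equal-moments convention).

The population is modelled per timepoint as a two-component Gaussian
mixture on circularity — component 1 the rods, component 2 the spheres,
enforced by the `mu1 <= mu2` ordering after fitting.  EM is initialised by
a split at the 40th percentile (cell populations here are rod-heavy),
standard deviations are floored at 1e-3 against collapse, convergence is a
log-likelihood gain below 1e-8, and the full log-likelihood trace is kept
so monotonicity is checkable on every fit.  The Gaussian family on (0, 1]
is used without truncating the likelihood — the standard practice with
mixture tooling on bounded shape indices — with a post-hoc degeneracy flag:
Ashman's `D = sqrt(2) |mu2 - mu1| / sqrt(sigma1^2 + sigma2^2) < 2` marks
fits whose components do not form a clean bimodal split, which is what EM
converges to on genuinely unimodal data.  At 500 cells per timepoint the
planted `(w2, mu1, mu2)` are recovered within (±0.05, ±0.03, ±0.03) in at
least 95% of seeds.  Trajectories warm-start each timepoint from the
previous fit, and a minimum of 50 cells per timepoint is enforced (the
conventional floor for a per-timepoint estimate; overridable with a
warning).  The gas-vesicle index is simply the median per-cell mean
intensity — robust to the bright outliers that vesicle clumps produce.

## Metabolite filters and concordance

Features are kept when a Welch t-test on log abundances between EARLY and
STATIONARY gives `p < 0.001` *and* the phase-mean ratio in either direction
is at least 3 (inclusive).  The original per-feature p-values came from a
chromatography pipeline that is out of scope here; the Welch test on logs
is the substitute and is documented as such.  Replicates that are exactly
constant in both phases get `p = 0` when the means differ (perfect
separation) and `p = 1` when they agree; a zero phase mean opposite a
non-zero one counts as infinite fold and passes the fold rule, with a
message.  Concordance between a metabolite and a gene group is the Pearson
correlation of their standardized three-phase profiles (a Spearman variant
is available); with three values this is the natural — and admittedly
coarse — measure, so scores should be read as pattern agreement, not
evidence of regulation.

## What the simulators emulate, and what they do not

The generators reproduce the *structure* of the study this package is
built around: ~2400 genes, seven sampling points spanning all four phases,
duplicate cultures with one dye-flip pair per point, five temporal
archetype classes planted over a null background, additive plus
multiplicative measurement noise matched to the significance module's error
model, two-component circularity mixtures per timepoint, and metabolite
features with planted three-phase patterns.  Default planted class sizes
(451, 772, 10, 4, 18, remainder null) mirror the reported class
memberships of the five patterns.  Archetype templates are
piecewise-constant over phase segments — steps swing ±effect/2 between the
growing and late segments, pulses deviate by the full effect in their
active segment — because that is how the patterns are described
qualitatively and it keeps truth labels unambiguous.  The default effect of
1.0 log10 units and noise scales `sigma_add = sigma_mult = 0.1` are
calibrated so that recovery tests are meaningful (strong but not trivial
signal), not to mimic any real array's effect-size distribution, which is
unknown.  Growth uses a logistic with a smooth Baranyi-style lag (OD
strictly increasing from exactly the inoculation density, 0.02 by default)
and an optional delayed secondary rise emulating the late optical-density
increase from accumulating gas vesicles.

Consequences for interpretation: passing recovery tests shows the pipeline
is correct and well-calibrated *under its own error model and
piecewise-constant truth*.  Real arrays add spatial artifacts, dye bias
beyond what a flip cancels, correlated genes, and smooth temporal
profiles; real cell images add segmentation error upstream of the
morphology table.  None of those are simulated, and no test here speaks to
them.

## Numerical choices and problem sizes

Degenerate inputs fail loudly and specifically: duplicate gene ids,
non-numeric cells, negative lambdas, constant rows (named), empty phases
(named), non-positive OD.  Simulators save and restore the global RNG
state, so they are pure functions of parameters and seed, and the pipeline
driver is byte-deterministic given config and seed.  The test suite runs at
deliberately moderate sizes — 10,000 null genes for lambda calibration,
1000 genes for permutation calibration, 5000 genes for error-model
recovery, 100 seeds at 500 cells for mixture recovery, 1000 random matrices
for the run-scan and sweep property checks — chosen so the whole suite
completes in about a minute while keeping Monte-Carlo error well inside
each asserted tolerance.

## Known limitations

* The lambda statistic's chi-square calibration is asymptotic in a weak
  sense (plug-in variance at the observed level); at 2 replicates it is
  accurate at the 95th percentile but a heavy-tailed error distribution
  would mis-calibrate it.
* Class-level K-means cannot resolve planted classes much smaller than
  `n_genes / K`.
* The three-phase concordance score has two degrees of freedom; it ranks
  candidate gene groups but cannot multiple-test across a genome.
* The four-phase partition depends on `f_exp`/`f_stat`; curves sampled too
  sparsely around the transition can shift a boundary by one point, which
  is why both fractions travel with every annotation.
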
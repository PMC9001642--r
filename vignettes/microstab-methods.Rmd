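---
title: "Models and methods behind microstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind microstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`microstab` implements the complete ecological-inference workflow used to
study how a perturbation (for instance, carbon-source addition to an
aquaculture system) reshapes bacterial communities across connected
habitats — rearing water, biofloc aggregates, and the animal gut. This
vignette explains each model, its assumptions, the tunable parameters, and
the design decisions taken where the methodological literature leaves the
choice open. Every empirical claim below is one that the package's own test
suite or `scripts/acceptance.R` recomputes.

## Data model

All statistics operate on a plain numeric matrix of non-negative integer
counts, samples in rows and OTUs in columns, with unique ids as dimnames
(`validate_otu_table()`). Sample metadata is a data frame with `sample_id`,
`group` (treatment arm) and `habitat`. Trees are `ape::phylo` objects whose
tips cover the OTUs used in phylogenetic computations.

Rarefaction (`rarefy_counts()`) subsamples without replacement to a fixed
depth; samples below the target depth are dropped with a warning rather
than imputed, because a low-coverage library carries no information about
its missing reads. The default depth of 18,400 reads mirrors the common
convention for amplicon libraries of this study design; the synthetic
fixtures use far smaller depths (hundreds to thousands), which exercises
identical code paths.

## Diversity and ordination

Richness is the count of observed OTUs; Pielou evenness is natural-log
Shannon over `log(richness)` (0 by convention for a single-OTU sample);
Faith PD is the branch length spanned by the present tips including the
path to the root (the root-inclusive convention; basal polytomies are
resolved with zero-length edges before the computation, which leaves the
total unchanged). Bray–Curtis, ANOSIM, PERMANOVA and the within-group
centroid distances are delegated to `vegan` (`vegdist`, `anosim`,
`adonis2`, `betadisper`); permutation p-values use the `(b + 1)/(n_perm +
1)` convention with a default of 999 permutations, and group-wise families
of pairwise comparisons are Benjamini–Hochberg adjusted per panel. The
within-group dispersion uses the principal-coordinate centroid convention
(with the imaginary correction for negative eigenvalues) because the
alternative — mean pairwise dissimilarity — is not an equivalent quantity
and the choice must be stated; the centroid convention is the one that the
field's standard implementation (`betadisper`) defines.

## Taxon partitioning

Over a `group x habitat` design, an OTU is *present* in a cell when it has
a positive count in at least `min_samples` samples (default 1, the
permissive reading of "occurring"; a prevalence floor is exposed because
occurrence definitions in the literature rarely state one). Detected OTUs
partition into:

* **core** — present in every cell;
* **sample_specific** — detected in a strict subset of habitats,
  regardless of group;
* **group_specific** — everything else (full habitat coverage overall but
  not every cell).

The habitat-subset rule takes precedence: an OTU missing a habitat
everywhere is sample-specific even if confined to one group. One corner
case the verbal definitions do not cover is an OTU seen in all three
habitats but never in all habitats of a single group (e.g., water only in
group 1, biofloc only in group 2, gut only in group 3); assigning the
remainder to `group_specific` keeps the three classes an exact partition
of the detected OTUs, which downstream bookkeeping relies on.

Levins' niche breadth for OTU *j* is `B_j = 1 / sum_i P_ij^2`, where
`P_ij` is the share of OTU *j*'s total abundance found in sample *i* —
an inverse-Simpson concentration ranging from 1 (one sample) to the number
of samples (perfectly even). It is computed on the pooled sample set by
default, with an optional grouping argument.

## Differential abundance

`diff_abundance()` is a deliberately simplified negative-binomial Wald
test, documented as an approximation of the DESeq2-style workflow rather
than a clone: median-of-ratios size factors (with a positive-count
fallback when no OTU is observed everywhere), method-of-moments dispersion
pooled within conditions and shrunk 50% toward a fitted `a0 + a1/mu`
trend, a delta-method standard error for the log2 fold change of
normalized condition means (with a 0.5 pseudo-mean guarding OTUs absent
from one arm), normal Wald p-values and BH adjustment. There is no outlier
replacement and no independent filtering. Under a null with matched
negative-binomial arms the raw type-I error sits near the nominal 5%
(recomputed by the acceptance script), and an 8-fold planted enrichment at
n = 6 vs 6 and 10k depth is detected for the large majority of planted
OTUs.

## SparCC networks

Compositional data make naive correlations spurious, so co-occurrence
edges come from the log-ratio variance estimator: per iteration, fractions
are drawn from a per-sample Dirichlet posterior (counts + 1), the variance
matrix `t_ij = var(log x_i/x_j)` is formed, basis variances solve the
sparsity-approximation linear system, and correlations follow as
`(w_i + w_j - t_ij) / 2 sqrt(w_i w_j)`, clamped to `[-1, 1]`. Up to 10
strongly correlated pairs (|rho| above 0.1) are iteratively removed from
the approximation system, and the reported matrix is the elementwise
median over 20 Dirichlet iterations — "the median of 20 iterations" in the
estimator's usual sense. Pseudo p-values come from bootstraps that shuffle
each OTU's counts independently across samples (marginals kept, covariance
destroyed); the per-bootstrap iteration count defaults to 5 for tractable
resampling, which leaves the observed estimate's 20-iteration median
untouched. OTUs are pre-filtered to a mean of >= 5 reads
(`filter_mean_reads()`), and edges require `|rho| >= 0.6` (inclusive) and
`p < 0.05`.

Network metrics are delegated to `igraph`. Module detection uses greedy
modularity maximization for determinism (Louvain-style methods reorder
with thread and seed state); the membership argument lets any partition be
substituted. Closeness uses the harmonic convention because thresholded
co-occurrence networks are routinely disconnected. On the planted-hub
fixtures, the within-module degree z-score (Zi) and participation
coefficient (Pi) reproduce their analytic values (an evenly spread
degree-8 connector across 4 modules has `Pi = 0.75` exactly), and the
classification thresholds are the standard `Zi > 2.5` / `Pi > 0.62`.
Note that Newman modularity is bounded by 1; reported "modularity" values
above 1 in parts of the applied literature must refer to some unstated
normalized quantity, and this package makes no attempt to reproduce them.

## Stability: cohesion and natural connectivity

Connectedness of taxon *i* is the mean of its significant positive (resp.
negative) correlations, using the same significance mask as the network
(`|rho| >= 0.6`, `p < 0.05`); per-sample cohesion is the
abundance-weighted sum `sum_i a_si * conn_i`, yielding a positive and a
negative cohesion per sample and their `|negative|/positive` ratio. The
taxa-shuffle null correction of the original cohesion formulation is a
different estimator of connectedness; the mask-based form is used here
because it is the one consistent with the network construction, and the
brute-force equality check in the tests pins the arithmetic to 1e-12.

Natural connectivity is `ln((1/N) sum_i exp(lambda_i))` over the
eigenvalues of the binarized, sign-stripped adjacency — the robustness
literature defines it on simple graphs, and whether signs or weights
should enter is not settled, so the simple-graph form is the default.
A log-sum-exp evaluation is mandatory: `exp(lambda_max)` overflows beyond
roughly `lambda_max > 700`, which real hub-rich networks reach easily.
Robustness curves remove `ceiling(f * |target|)` nodes uniformly at random
from a target set (all, core, or specific nodes) over a grid of fractions
(default 0 to 0.95 by 0.05, 100 repetitions), reporting mean and sd.

## Community assembly

betaMNTD between two communities is the abundance-weighted mean distance
from each taxon to its nearest taxon in the opposite community (0 for
shared taxa); betaNTI is its z-score against a null that shuffles taxa
labels across the tips of the phylogeny. Each shuffle permutes the
distance matrix once and serves every sample pair, which keeps the null
count per pair intact while touching the tree once per shuffle. The
abundance-weighted form is the default (the common choice in this
literature); an unweighted switch exists. The null count defaults to 999
for both betaNTI and RC; the detection limit of the Sloan model defaults
to one read at the sample depth.

RC (Bray–Curtis Raup–Crick) compares the observed dissimilarity with
dissimilarities of null community pairs that preserve each sample's
richness and total abundance while drawing taxa by metacommunity occupancy
and filling individuals by metacommunity relative abundance, scaled to
`[-1, 1]`. The two-step null generator is exported
(`rc_null_community()`) so the index can be calibrated by
self-consistency: pairs generated by the null process itself give
`|RC| > 0.95` at close to the nominal 5% rate. Pairs of multinomial draws
from a fixed metacommunity are systematically *more* similar than this
null (RC skews negative), which is the expected behavior of the index,
not a defect: RC asks whether turnover deviates from stochastic assembly,
and replicate draws from one urn are less turned over than re-assembled
communities.

Process labels follow the usual decision rule — `betaNTI > 2`
heterogeneous selection, `< -2` homogeneous selection, otherwise
`RC > 0.95` dispersal limitation, `< -0.95` homogenizing dispersal, else
undominated. The undominated (drift) remainder is kept as an explicit
fifth class so that fractions always sum to 1.

The Sloan neutral model predicts a taxon's occurrence frequency across
local communities from its source-pool share `p` as
`F(p) = 1 - BetaCDF(d; Nmp, Nm(1-p))`; `Nm` is fitted by bounded least
squares on the occurrence curve, `R^2 = 1 - SS_res/SS_tot` may be negative
(read: the neutral model does not describe assembly), and taxa are classed
above/neutral/below a 95% Wilson interval around the predicted frequency
at the observed number of local communities.

## Source apportionment

`gibbs_source_apportion()` is a collapsed Gibbs sampler over latent
per-read source labels with an explicit unknown environment (no training
counts): `P(z = s) ~ (m_st + nhat_st + alpha_s)/(m_s. + nhat_s. +
alpha_s T) * (n_s + beta)`. Hyperparameters follow the published
microbial source-tracking defaults (`alpha_source = 0.001`,
`alpha_unknown = 0.1`, `beta = 10`), sinks are subsampled to 1,000 reads
by default, and estimates average 50 retained draws (every 10th sweep
after a 100-sweep burn-in) over 5 independent restarts, with the
between-restart spread reported as a convergence diagnostic. The per-read
sweep is implemented in C++; a small systematic mass (typically a few
percent) drifts to the unknown environment even for fully explained
sinks — a known property of the unknown-source prior, visible in the
acceptance numbers as estimates of roughly 0.55/0.39 for a true 0.6/0.4
mixture.

## Synthetic data: what it emulates and what it does not

Every generator is a pure function of its parameters and a seed, and ships
its ground truth:

* `simulate_multihabitat_experiment()` — a 3-group x 3-habitat
  Dirichlet-multinomial design with the unbalanced replication of the
  motivating study (6 per cell; 4 water and 2 biofloc in the control
  group), a convergence dial `kappa` mixing shared and habitat-private
  profiles, and planted core / habitat-private / group-private OTU sets.
  Core OTUs carry an abundance floor so that they occur in every cell at
  the default depth (5,000 reads, concentration 50) — this is what makes
  exact core recovery a meaningful oracle rather than a coin flip.
* `simulate_neutral_community()` — Hubbell zero-sum dynamics with
  migration `m`; burn-in 20N steps and census spacing N steps (standard
  quasi-stationarity practice; the primary literature gives no guidance).
  Because consecutive censuses of one community retain temporal
  autocorrelation, the Sloan fit recovers `m` with an upward bias of
  roughly a third at `m = 0.1` — well inside the 50% relative-error band
  used in the tests, but worth knowing.
* `simulate_selected_communities()` — Brownian trait on a pure-birth
  tree, Gaussian habitat filters. Detecting *homogeneous* selection
  requires communities that occupy a small, clustered fraction of a deep
  taxon pool and that turn over among close relatives between replicates;
  the fixture therefore uses 800 tips, filter width 0.35 trait-SD around
  an optimum at 1.5 trait-SD, per-sample Dirichlet turnover
  (concentration 0.03) and base-abundance spread 0.2. Shallower pools or
  wider filters leave median betaNTI above -2 because the tip-shuffle
  null cannot distinguish a community that covers half the tree from a
  random one. Heterogeneous selection (optima at -2 and +2 trait-SD) is
  far easier and robustly yields medians above +2.
* `simulate_compositional_counts()` — log-normal basis abundances with a
  prescribed correlation matrix, closed to the simplex, multinomial
  counts; the planted-pair and identity-basis fixtures validate SparCC.
* `simulate_source_sinks()` — multinomial sinks from known mixtures, with
  the unknown profile supported on taxa absent from all sources so the
  unknown fraction is identifiable.
* `simulate_planted_network()` — stochastic block models with injected
  hubs and connectors for the Zi–Pi and robustness fixtures.

None of the generators emulates sequencing error, chimeras, taxonomic
misassignment, or compositional bias from copy-number variation, so
passing recovery tests demonstrates correctness of the statistics, not
robustness of the laboratory pipeline upstream of the OTU table.

## Null-model calibration design

Type-I error checks use one statistic per simulated dataset: the betaNTI
calibration simulates 100 independent no-signal pairs (fresh
abundance-to-tip assignment each time, depth 400 over 60 tips — deep
enough that presence sets differ and the null sd is positive), and the RC
calibration draws observed pairs from the exported null process itself.
Computing one z per pair matters: the many pairs of a single dataset share
one abundance-to-tip realization and are strongly dependent, so their
joint exceedance rate is not a calibration check. ANOSIM, PERMANOVA
(199 permutations) and the NB-Wald test are calibrated over 200 null
datasets each.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run the full battery at desk
scale — e.g., SparCC at 50 OTUs x 60 samples x 20k depth, betaNTI nulls of
299–999 shuffles, 100-pair calibrations, 200-dataset type-I batteries, and
an end-to-end pipeline on the 46-sample multihabitat fixture — sizes
chosen so any stage can be re-run interactively while still giving the
recovery statistics room to concentrate. Every stochastic step takes an
explicit seed; the pipeline derives all stage seeds from one master seed
and twice-run configurations produce byte-identical output trees (checked
file-by-file in the tests).

## Known limitations

* The NB-Wald test's normal approximation is slightly anti-conservative
  at very small means; it is intended for rarefied tables where
  low-count OTUs have been filtered for the network anyway.
* Sloan fits on censuses of a single simulated community inherit temporal
  autocorrelation (see above); fits on real replicate communities do not
  have this particular bias.
* The unknown-source prior absorbs a few percent of explained sink mass;
  comparisons between groups are unaffected, absolute proportions are
  conservative.
* RC against field data should be interpreted with the self-consistency
  caveat above: replicate-like pairs legitimately skew negative.
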
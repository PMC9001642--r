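# microstab

Stability and assembly analysis of multi-habitat microbial communities.

`microstab` is an R package for the complete ecological-inference workflow
applied to OTU count tables from connected habitats — for example rearing
water, biofloc aggregates and shrimp gut in an aquaculture system under
different carbon-source regimes. It asks, and answers quantitatively, the
three questions such studies turn on:

1. **Do communities converge across habitats?** Rarefaction, alpha
   diversity (richness, Pielou evenness, Faith PD), Bray–Curtis
   ordination (PCoA), ANOSIM / PERMANOVA with BH-adjusted pairwise panels,
   within-group dispersion, Venn sharing, core / group-specific /
   sample-specific taxon partitioning, a simplified negative-binomial Wald
   test for differential abundance, Levins' niche breadth
   (`B_j = 1 / Σ_i P_ij²`), and Gibbs-sampling source apportionment with
   an unknown-source environment.
2. **Do their co-occurrence networks become more stable?** SparCC
   compositional correlations (median of 20 Dirichlet iterations, 100
   bootstrap pseudo p-values), networks thresholded at `|ρ| ≥ 0.6`,
   `p < 0.05`, topology and modularity, per-sample cohesion
   (`Σ_i abundance_i × connectedness_i`), natural connectivity
   (`λ̄ = ln((1/N) Σ e^{λ_i})`) with robustness curves under random node
   removal, and Zi–Pi keystone classification (module hubs `Zi > 2.5`,
   connectors `Pi > 0.62`).
3. **Which assembly processes dominate?** Abundance-weighted βMNTD/βNTI
   against tip-shuffle nulls, Bray–Curtis Raup–Crick (`RC ∈ [-1, 1]`),
   the standard five-way process partition (heterogeneous / homogeneous
   selection, dispersal limitation, homogenizing dispersal, undominated),
   and the Sloan neutral model
   (`F(p) = 1 − BetaCDF(d; Nmp, Nm(1−p))`) with fitted migration rate
   `m`, `R²`, and per-OTU neutrality classes.

Because the statistics are only trustworthy when they recover known
answers, the package also ships first-class synthetic-data generators with
ground truth for every stage: multi-habitat Dirichlet-multinomial designs
with planted core/specific taxa, Hubbell neutral dynamics with known `m`,
trait-filtered communities on simulated phylogenies, compositional counts
with planted basis correlations, source/sink mixtures with known
proportions, and stochastic block models with planted hubs and connectors.

## Worked example

Simulate the unbalanced 3-group × 3-habitat design, partition taxa,
build one group's SparCC network, and compute cohesion:

```r
library(microstab)
sim    <- simulate_multihabitat_experiment(seed = 42)
counts <- rarefy_counts(sim$counts, depth = 5000, seed = 1)

cl <- classify_otus(counts, sim$metadata)
table(cl$class)
#>            core  group_specific sample_specific
#>              15               9              44

cn15 <- filter_mean_reads(counts[sim$metadata$group == "CN15", ])
rho  <- sparcc(cn15, n_iter = 20, seed = 1)
pv   <- sparcc_pvalues(cn15, rho, n_boot = 50, seed = 2)
net  <- build_network(rho, pv, rho_min = 0.6, alpha = 0.05,
                      node_classes = ifelse(cl$class == "core",
                                            "core", "specific"))
tm <- topology_metrics(net)
#> nodes 12  edges 10  avg degree 1.67  modularity 0.505

conn <- connectedness(rho, pv)
coh  <- cohesion(relative_abundance(
          counts[sim$metadata$group == "CN15", conn$otu_id]), conn)
head(coh, 3)
#>      sample_id  positive   negative     ratio
#> 1 CN15_water_1 0.1217487 -0.3011826 2.4738062
#> 2 CN15_water_2 0.1888048 -0.3656363 1.9365833
#> 3 CN15_water_3 0.2919659 -0.2663887 0.9123964
```

The classifier recovers exactly the 15 planted core OTUs; the cohesion
table gives each sample's positive and negative cohesion and their
`|negative|/positive` ratio, the package's per-sample stability score.
`run_pipeline(pipeline_config(...))` chains every stage (rarefy →
diversity → partition → network → stability → assembly → source
tracking) under one master seed and writes per-stage TSVs, a JSON
summary, and a run log; reruns are byte-identical.

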
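# otoconnect

Two-stage otolith-microchemistry analysis of fish population
connectivity, for fisheries scientists working with LA-ICP-MS and
solution-based (WS-ICP-MS) otolith element data.

Otoliths grow incrementally and take up trace elements from the ambient
water, so different regions of one otolith record different life stages.
`otoconnect` turns that record into connectivity estimates in two stages:

1. **Natal-source inference** from near-core laser-ablation chemistry by
   *unsupervised random-forest clustering*: a synthetic reference is drawn
   from the product of the empirical element marginals, a forest is
   trained to tell observed from synthetic rows, the tree-co-occurrence
   proximity `s_ij` becomes a dissimilarity `d_ij = √(1 − s_ij)`, which is
   clustered by partitioning around medoids (PAM) with the number of
   clusters scored by the Dunn index.
2. **Bayesian mixed-stock assignment** of adults to a juvenile
   whole-otolith baseline. Site signatures are multivariate normal with
   conjugate Normal–Inverse–Wishart priors, adult origins follow a
   mixture with Dirichlet(α = 1) proportions, and a Gibbs sampler redraws
   the site parameters every sweep so *baseline uncertainty propagates
   into the assignment*:

   - `z_i | π, θ ∝ π_j · N(x_i; µ_j, Σ_j)`
   - `π | z ~ Dirichlet(α + n_1, …, α + n_J)`
   - `(µ_j, Σ_j) ~ NIW posterior of site j`

   Adults are assigned to a site when its posterior probability exceeds
   0.5, else to a region whose sites' summed probability exceeds 0.5,
   else left unassigned.

Supporting modules cover LA-ICP-MS calibration (blank subtraction,
bracketing-standard drift correction, Longerich-style internal
standardization, Ca-ratio normalization), nonparametric spatial
statistics (Kruskal–Wallis, Dunn post hoc with compact letter displays,
Spearman trends, Wilcoxon matched pairs), supervised random-forest site
discrimination with out-of-bag confusion and permutation importance, a
seeded synthetic-data generator emulating a ten-site North Sea survey
design, and a one-command pipeline. See the methods vignette
(`vignettes/otolith-connectivity-methods.Rmd`) for the models,
assumptions, and design choices.

## Worked example

```r
library(otoconnect)

cfg    <- scenario_preset("study_default")          # 10-site survey design
juv    <- generate_juveniles(cfg, seed = 1)         # near_core/edge/whole zones
adults <- generate_adults(cfg, n_per_area = 20, seed = 1)
juv
#> <otolith_dataset> 700 records, 430 fish, elements Mg,Mn,Ba,Sr [ug_g]
#>   zones:  edge=135  near_core=135  whole=430

## latitudinal trends in edge chemistry (per fish)
spatial_stats_table(juv, zone = "edge")$trend
#>   element        rho      p_value
#> 1      Mg -0.3316465 8.517410e-05
#> 2      Mn -0.7578178 1.965623e-26
#> 3      Ba  0.4810899 3.500747e-09
#> 4      Sr  0.4115214 7.104650e-07

## stage 1: natal clustering of near-core chemistry (k fixed to 4)
cl <- natal_clustering(juv, k_range = 2:8, n_trees = 1000, seed = 1,
                       override = 4)
cl$solution
#> <cluster_solution> k = 4, objective = 121.2231, sizes: 38/33/35/29
#>   Dunn index = 0.638

## stage 2: assign adults to the whole-otolith baseline
ar  <- fit_mixed_stock(baseline_model(juv), adults, chains = 2,
                       iters = 2000, burn = 500, thin = 2, seed = 1)
dec <- threshold_classify(ar, default_region_map(), tau = 0.5)
round(attr(dec, "summary"), 2)
#>       site     region unassigned
#>       0.50       0.44       0.05
```

The trend table shows the built-in geography of the simulated survey —
Mn falling and Ba rising with latitude — detected from the generated
data. The cluster solution partitions the 135 ablation fish into four
natal sources with their Dunn-index profile; `cl$summary` holds each
cluster's mean ± SD signature and the per-site source contributions. The
assignment summary says 50% of adults exceeded the 0.5 threshold for a
single nursery site, a further 44% for a region, and 5% matched nothing
(these fractions are properties of the synthetic scenario's overlap, not
of any real survey). `contribution_summary(dec)` and
`posterior_contributions(ar)` break composition down per sampling area.

`run_pipeline(pipeline_config(scenario = "study_default", seed = 1),
out_dir = "out/")` runs all stages and writes the report tables
(confusion and importance tables, Dunn profile, cluster signatures and
contributions, posterior probabilities, decisions, per-area
contributions, MCMC diagnostics) plus a JSON summary and run log; a rerun
with the same seed is byte-identical. A thin CLI wrapper lives at
`inst/cli/otoconnect.R` (`simulate` and `run` subcommands).

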
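# poolnet

Multi-scale analysis of species co-occurrence networks: network modules,
multivariate clusters, and the agreement between them.

## The problem

When species' presences are recorded across many sampling sites, two very
different families of methods partition the species pool into subgroups:

* **Network modules** — build the unweighted, unipartite co-occurrence graph
  (an edge wherever two species share at least one site) and maximise
  Newman–Girvan modularity

  $$Q = \sum_c \left[\frac{L_c}{m} - \left(\frac{D_c}{2m}\right)^2\right]$$

  by spin-glass simulated annealing, where $m$ is the edge count, $L_c$ the
  edges inside group $c$ and $D_c$ its summed degree.

* **Multivariate clusters** — compute the species-by-species Jaccard
  dissimilarity $d_{ab} = 1 - |A \cap B| / |A \cup B|$ over site sets and
  partition around medoids (PAM), with the number of clusters $k$ set either
  to the module count or to the gap-statistic optimum.

Whether these two partitions agree — and whether either reflects biotic
interactions rather than environmental filtering — is the scientific
question this package operationalises, with three comparison instruments:

1. **Congruence** $C$: the maximum proportion of species co-assigned by the
   two partitions over all one-to-one label matchings ("cluster rotations"),
   with a size-preserving permutation test.
2. **Spatial clustering**: interpolate each species' range centroid (mean of
   its occupancy-unit centroids, planar km), compare mean pairwise centroid
   distances within groups ($MD_{within}$) and among groups ($MD_{among}$),
   and test the ratio against an MRPP-style permutation null. Ratios below 1
   indicate spatially aggregated groups — a filtering signature.
3. **Nest-associate benchmarking**: for a declared host + associate complex
   (e.g. a nest-building chub and its associate minnows), compute the
   *completeness* of the complex inside any partition and contrast the
   pairwise co-occurrence *effect sizes* $(obs - \mathbb{E}[obs])/N$ — from
   the exact hypergeometric co-occurrence model — of host–associate pairs
   against the whole network.

A synthetic-data generator plants group-structured occurrences, clustered
range centroids and a host-conditional associate complex with known ground
truth, so every stage is testable without any external data.

## Worked example

```r
library(poolnet)

cfg <- synthetic_config(n_sites = 90, n_groups = 3, species_per_group = 8,
                        p_in = 0.9, p_out = 0.005, group_sep_km = 150,
                        sigma_km = 30, n_units_per_species = 15, seed = 4)
sim  <- generate_occurrences(cfg)
tabs <- generate_centroid_tables(cfg, sim$truth)

report <- run_basin_analysis(
  sim$occurrence, units = tabs$units, occupancy = tabs$occupancy,
  config = pipeline_config(n_perm = 999, b_refs = 20, k_max = 6, seed = 2),
  basin = "demo", scale = "toy")
report
#> <poolnet_basin_report: demo (toy)>
#>   90 sites, 24 species (0 isolated), 3 modules (Q = 0.388), k_opt = 3
#>   C = 1.000 (p = 0.001)

tidy(report)[, c("n_modules", "q", "c", "c_p", "gs_k",
                 "md_modules_ratio", "md_modules_p")]
#>   n_modules         q c   c_p gs_k md_modules_ratio md_modules_p
#> 1         3 0.3883398 1 0.001    3       0.06951306        0.001
```

Reading the row: annealing found the three planted habitat groups
(`n_modules = 3`, modularity `Q = 0.39`); PAM at `k = 3` produced an
identical partition (`C = 1`, permutation `p = 0.001`, i.e. no random
regrouping matched as well); the gap statistic independently selected
`k_opt = 3`; and species in the same module have range centroids ~14× closer
to each other than to other modules' species (`MD` ratio `0.07`,
`p = 0.001`) — exactly the planted spatial clustering.

Individual stages are plain functions on tabular data and compose with the
pipe: `occurrence_matrix()`, `build_edge_list()`, `jaccard_dissimilarity()`,
`detect_modules()`, `pam_cluster()`, `gap_statistic()`, `congruence_test()`,
`species_centroids()`, `spatial_test()`, `completeness()`,
`effect_contrast()`. Results carry `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` figures. A small command-line wrapper
(`inst/scripts/poolnet.R`) exposes `simulate` and `run` subcommands.

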
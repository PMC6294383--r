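---
title: "Methods: co-occurrence networks, clusters, and the comparisons between them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence networks, clusters, and the comparisons between them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolnet)
```

poolnet partitions a species pool two ways from the same site-by-species
presence–absence matrix — network modules and multivariate clusters — and
quantifies how, and why, the two partitions differ. This vignette records
the models, the tunable parameters, the numerical choices, and the limits of
what the synthetic tests demonstrate.

## From incidences to two partitions

**Validation.** Species observed at no site and sites holding no species are
dropped before any analysis (with a warning and an audit attribute): an
unobserved species can join no edge, no cluster and no centroid. A basin
with fewer retained sites than `min_sites` signals a distinct
"insufficient samples" condition so that pipelines can distinguish an
under-sampled basin from a malformed file. Typical thresholds are 70 sites
for medium-scale basins and 35 for small-scale basins, supplied per scale.

**Network route.** Two species are linked if they share at least one site.
The graph is simple, unweighted and unipartite; shared-site counts are kept
on the edge list only so the effect-size model can reuse them. We
deliberately do not threshold edges by co-occurrence significance — every
observed co-occurrence is an edge. Modules maximise Newman–Girvan
modularity by spin-glass simulated annealing (Potts model, `gamma = 1`, no
negative-link term, since the graphs are unweighted). Defaults: 100 spins,
start temperature 1, stop temperature 0.01, cooling factor 0.99. The search
is stochastic, so the seed is an explicit argument; `restarts` re-runs the
annealing and keeps the best-modularity solution. Spin-glass annealing
requires a connected graph; disconnected networks are handled per connected
component with label offsets, which keeps every non-isolated species
labelled and leaves modularity well defined on the full graph. Isolated
species (no edges at all) are excluded from module detection and from all
partition comparisons, and reported in an audit list — the alternative,
one singleton module each, would distort both the congruence matching and
the spatial test.

**Cluster route.** Jaccard dissimilarity is computed *between species*
(the matrix is transposed before the distance call) because it is species,
not sites, being partitioned. PAM then runs its greedy BUILD seeding
followed by SWAP descent to a local optimum in which no single
medoid/non-medoid exchange lowers the summed dissimilarity of species to
their medoids. Because the SWAP neighbourhood admits local optima that are
not global — on random small instances a single BUILD-started descent
demonstrably misses the enumerated optimum a few percent of the time — the
default adds four random-start descents (`nstart = 5`) and keeps the
lowest-cost solution; each returned solution still satisfies the
swap-local-optimality contract, which the test suite checks exhaustively.
Assignment ties (a species equidistant from two medoids) break toward the
lower species index for determinism.

## Choosing k: the gap statistic on a dissimilarity matrix

The classical gap construction draws reference data in feature space, which
a dissimilarity matrix does not have. We therefore embed the species by
classical multidimensional scaling, retaining the leading components that
carry at least 95% of the positive eigenvalue mass (Jaccard is
non-Euclidean, so negative eigenvalues occur and are discarded), draw
reference points uniformly within the embedding's bounding box, and
recompute Euclidean dissimilarities for each of `b_refs` (default 50)
reference sets. Dispersion `W_k` is PAM's own objective, so the observed
and reference quantities optimise the same criterion. Selection uses the
one-standard-error rule — the smallest `k` with
`gap(k) >= gap(k+1) - se(k+1)` — with the global maximum available behind
`rule = "globalmax"`; which variant original analyses of this kind used is
typically unstated, and the 1-SE rule is the conservative standard choice.
`k_opt = 1` is a legal outcome and downstream stages treat it as "among
group comparisons impossible" rather than an error.

## Congruence between partitions

Group labels are arbitrary on both sides, so congruence is the *maximum*
proportion of co-assigned species over one-to-one matchings of cluster
labels onto module labels. With `k` groups each, that is the `k!` label
rotations; the implementation enumerates them when the smaller side has at
most 6 labels (recording how many matchings were examined — 6 for a 3×3
comparison) and otherwise solves the identical optimum as a maximum-weight
bipartite assignment on the group-by-group contingency table. When the two
partitions have different group counts the matching is injective from the
smaller label set, unmatched groups contribute nothing, and the result is
flagged as an extension — in that situation `C = 1` is impossible by
construction, which is why the pipeline skips the congruence test when the
gap-optimal `k` differs from the module count.

The permutation test shuffles species across the second partition's groups
holding group sizes fixed — the strictest reading of "randomising
assignments within clusters" — and reports the add-one p-value
`(count + 1)/(n_perm + 1)` (never exactly zero) alongside the raw
proportion, which supports the conventional "p < 0.001" phrasing at 999
permutations.

## Spatial clustering of range centroids

A species' range centroid is the unweighted mean of its occupancy-unit
centroids in planar, equal-area-projected kilometres; no geodesic
computation is attempted, so coordinates must be projected beforehand.
`MD_within` pools all same-group species pairs (unweighted by group size;
singleton groups contribute only among-group pairs), `MD_among` pools all
different-group pairs, and their ratio is the headline statistic: below 1
means spatially aggregated groups. A size-weighted MRPP delta
(`sum_g n_g/N * mean within-group distance`) is also computed, and the test
can use it as the statistic for comparability with standard MRPP routines;
the test suite cross-checks it against vegan's implementation.

One directionality subtlety deserves a record. A literal rule sometimes
quoted for such tests — "the proportion of permutations in which
`MD_within >= MD_among`" — does not reference the observed arrangement at
all: under any null it hovers near 0.5 for overlapping groups and cannot
produce small p-values for clustered data. We therefore implement the
standard MRPP convention, the proportion of permutations whose statistic is
as small as or smaller than the observed one, and keep the literal rule
available behind `direction = "literal"` for audit only. The null never
re-simulates species' ranges: only group labels are permuted, holding every
centroid (hence every range) fixed.

## The nest-associate benchmark

A declared complex (one host, its associates) is scored two ways.
*Completeness* is the proportion of associates sharing the host's group;
associates absent from the basin's species pool are dropped from the
denominator (the complex can only be evaluated over species the basin
contains), while associates present but unpartitioned — isolated nodes —
count against it. *Effect contrast* summarises the standardized
co-occurrence effect `(obs − N1·N2/N)/N` over four pair sets:
host–associate pairs, within-group pairs, among-group pairs (the latter two
partition the network's pair set) and all pairs. The standardized form is
the default because it is bounded in [−1, 1] and comparable across basins
with different site counts; the raw difference is exposed as
`effect_raw`. Standard deviations use the sample (n−1) form. Tail
probabilities come from the exact hypergeometric law evaluated with
log-gamma arithmetic (`dhyper`/`phyper`), finite for thousands of sites.

## What the generator emulates — and what it does not

`generate_occurrences()` draws independent Bernoulli occurrences given a
site's habitat group (`p_in` at own-group sites, `p_out` elsewhere) and,
when a complex is planted, generates the host first and conditions each
associate only on host presence (`p_assoc_given_host` vs
`p_assoc_no_host`) — pure asymmetric dependence, the simplest mechanism
that produces the two confounded signals (habitat filtering and positive
association) in controllable doses. `generate_centroid_tables()` places
group centroid means on a circle with neighbouring means `group_sep_km`
apart (a line would make non-adjacent groups twice as distant) and draws
each species' occupancy units as isotropic bivariate normals
(`sigma_km`); `spatial_mode = "common"` or zero separation collapses to one
distribution. Units are per-species rather than a shared grid — centroid
interpolation is agnostic to sharing.

The generator does *not* emulate spatially autocorrelated site networks,
dendritic river topology, detection error, or abundance; passing tests
therefore demonstrate correctness of the algorithms under independence, not
robustness to those real-data features.

One genuine property of binary co-occurrence deserves emphasis, because it
shapes which synthetic regimes are informative. The probability that two
species of *different* groups share at least one site is
`1 − (1 − p_in·p_out)^(s_a + s_b) · (1 − p_out²)^(s_other)` over the site
counts involved, which saturates quickly: at 100 sites with `p_in = 0.9`
and `p_out = 0.05` cross-group pairs are linked ~95% of the time and the
unweighted graph is ~97% dense — it then carries essentially no modular
signal, and no optimizer can recover the planted groups from topology
alone. This is not an optimizer failure (the returned partitions' Q meets
or exceeds the planted partition's Q); it is the binary edge definition
discarding the information. The same mechanism limits perfect recovery of
a planted host complex: with `p_assoc_no_host = 0.05`, an associate's few
noise occurrences create real cross-edges, and the modularity-optimal
partition occasionally places one or two associates outside the host's
module. Demonstrations of module recovery therefore use sparser regimes
(e.g. `p_out` around 0.005 at 90–100 sites, which reproduces realistic
network densities of roughly 0.9 within groups and 0.2 between), and this
saturation behaviour is itself the reason analyses of this kind favour
smaller spatial scales.

## Numerical choices and problem sizes

* Per-stage seeds derive from one master seed via a fixed derivation
  (`sample.int` on a temporarily seeded RNG, restoring the caller's RNG
  state), so any stage can be re-run in isolation.
* Swap-optimality and cost comparisons use a 1e-12 absolute tolerance;
  exact probability identities are asserted to 1e-12.
* The add-one convention keeps permutation p-values in (0, 1]; raw
  proportions are reported alongside.
* The test suite sizes its simulations to run on one CPU in minutes:
  exhaustive co-occurrence enumeration up to 12 sites; exhaustive
  max-modularity search on graphs of up to 8 nodes (4140 partitions);
  permutation-test calibration with 500 replicates of 199 permutations at
  60–90 species; planted-recovery and nest-complex runs over 20 generator
  seeds; spatial power over 100 runs of 999 permutations. The acceptance
  script uses the same designs at 200 replicates / 50 runs.

## Known limitations

* Unweighted edges saturate with site count (above); abundance-weighted or
  significance-filtered networks are out of scope by design.
* The congruence permutation holds group sizes fixed; a reading that also
  randomises sizes would give a different (more liberal) null.
* The gap-statistic reference distribution depends on the MDS embedding of
  a non-Euclidean dissimilarity; with strongly non-Euclidean inputs the
  retained-eigenvalue rule (95% of positive mass) is a pragmatic, not
  canonical, choice.
* Range centroids summarise a whole range by one point; elongated or
  disjunct ranges are represented coarsely, and the spatial test inherits
  that coarseness.
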
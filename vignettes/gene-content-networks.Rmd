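---
title: "Gene-content networks and host associations in giant viruses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-content networks and host associations in giant viruses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncldvnet)
```

## The problem

Nucleocytoplasmic large DNA viruses (NCLDVs, phylum *Nucleocytoviricota*)
carry the largest genomes in the virus world. Their phylogeny is usually
summarized by trees built from a handful of near-universal core genes, but
those few genes say little about the evolution of the hundreds of other
genes each genome carries. `ncldvnet` analyzes gene *content* instead: it
takes an orthogroup membership table (every protein assigned to a cluster
of homologs, or left as an unclustered singleton), a genome metadata table
(family, intrafamilial lineage, host type, host eukaryotic supergroup) and
optionally a core-gene tree, and quantifies which taxa share which gene
repertoires, how cohesive each family's repertoire is, and which genes
track host type rather than phylogeny.

## The sharing statistic

All analyses start from presence/absence of taxa in orthogroups. For taxa
$i$ and $j$ (individual genomes, or whole family pangenomes obtained by
pooling the genomes of a family), let $U_{ij}$ be the number of orthogroups
present in both, and $T_i$ the number of orthogroups of $i$ present in at
least one *other* taxon of the matrix under analysis. The level of gene
sharing is

$$S_{ij} = \frac{U_{ij}}{\sqrt{T_i\,T_j}} \in [0, 1].$$

The geometric-mean normalization prevents a giant repertoire from drowning
out a small one, and counting only *shared* orthogroups in $T$ means that
genes private to a single taxon (including all singletons) never affect
$S$. Two numerical conventions matter. First, $T$ is always computed over
the taxon set of the matrix at hand, so genome-level and family-level $S$
values are intentionally not comparable across analyses. Second, a taxon
with $T = 0$ (it shares nothing with anyone) gets $S = 0$ against every
partner rather than `NaN`, so isolates flow through downstream code as
plain zeroes.

The sharing matrix defines a weighted undirected network: every taxon is a
node (isolates included), and every pair with $U_{ij} \ge 1$ is an edge of
weight $S_{ij}$. No weight threshold is applied by default; `min_weight`
exists only for sensitivity checks.

```{r sharing-example}
sim <- simulate_dataset(simulation_params(seed = 1))
counts <- build_count_matrix(sim$catalog, sim$meta)
sharing <- compute_sharing(counts)
sharing
```

## Markov Clustering

Genome networks are clustered with a from-scratch implementation of the
Markov Cluster algorithm: the column-stochastic flow matrix of the network
(with self-loops) is alternately *expanded* (squared, simulating a longer
random walk) and *inflated* (raised entrywise to the inflation exponent and
renormalized) until the flow stops changing; connected components of the
nonzero limit structure are the clusters. The tunable parameters:

* `inflation` (default **1.5**, dimensionless, must be > 1) — the
  granularity knob; larger values cut the network into finer clusters.
  1.5 is the conventional coarse setting for genome-content networks.
* `expansion` (default 2) — the matrix power; 2 is the standard choice.
* `prune_threshold` (default `1e-5`) — flow entries below it are zeroed
  each iteration and columns renormalized; at a few hundred nodes this is
  numerical hygiene, not a performance necessity.
* `self_loops` (default `"max"`) — each node receives a loop weighted at
  its largest incident edge before normalization, the common damping
  choice that prevents parity oscillations; `"one"` and `"none"` are
  provided for sensitivity analyses because graphical MCL front-ends do
  not document their loop policy.
* `tol` (`1e-6`) and `max_iter` (200) — convergence is declared when the
  largest entrywise change falls below `tol`; hitting `max_iter` returns a
  result flagged `converged = FALSE` with a warning rather than an error.

Cluster labels are assigned deterministically (numbered by each cluster's
lexicographically smallest member), so results are invariant to node input
order. Attractors — nodes that retain flow on the diagonal of the limit
matrix — are reported per cluster. Overlapping attractor systems cannot
occur in the component reading of the limit used here; the component
partition is what is returned.

```{r mcl-example}
clustering <- mcl_cluster(build_network(sharing, sim$meta))
clustering
```

## Intrafamilial variation and host diversity

Databases oversample some strains, so every per-genome quantity is first
averaged within intrafamilial lineages (roughly genus-level groups of most
related genomes); variation is then measured *between* lineages:

1. sample standard deviation (denominator $n-1$) of protein-coding gene
   counts across lineages — the sample convention is a deliberate choice
   where only "standard deviation" is conventionally specified, and is
   reported as missing for families with fewer than two lineages;
2. the same SD for unclustered singleton counts — only computable when a
   protein index accompanies the groups file, and reported missing (never
   zero) otherwise;
3. mean between-lineage patristic distance (substitutions per site) on the
   core-gene tree, where the distance between two lineages averages over
   all cross-lineage tip pairs, consistent with the genome-averaging
   principle (a `representative` mode using one tip per lineage exists for
   sensitivity checks).

Host diversity of a family is the Shannon index over the six eukaryotic
supergroups with known NCLDV hosts (Amoebozoa, Archaeplastida, Discoba,
Haptista, Opisthokonta, SAR):
$D = -\sum_j p_j \ln p_j$, with $p_j$ the proportion of the family's
lineages whose hosts fall in supergroup $j$; $D$ ranges from 0 to
$\ln 6 \approx 1.792$ nats. A lineage spanning several supergroups is
assigned its majority supergroup; an exact tie is a validation error that
forces an explicit decision, since lineages are expected to be
host-coherent.

```{r variation-example}
family_variation_report(sim$meta, sim$catalog, sim$tree)
```

## Host-association comparisons

To separate host effects from phylogenetic relatedness, comparisons are
made *across* a fixed family pair — every virus pair with one member from
each family sits at roughly the same phylogenetic distance. For a host
type, pairs where both viruses infect it are "similar", pairs where
exactly one does are "dissimilar", and pairs where neither does are
excluded. A one-sided Mann–Whitney–Wilcoxon test asks whether similar-host
pairs share more genes. Ties get midranks; when
$n_1 n_2 \le 400$ the p value is the exact conditional permutation tail,
computed by a counting dynamic program over the tie structure (base
`wilcox.test` refuses exact computation under ties), otherwise the normal
approximation with tie-corrected variance and continuity correction is
used. The switch point is configurable.

The orthogroup screen then identifies *which* genes track a host type: an
orthogroup is shared-by-target when at least one target-host virus of each
family carries it, and reported when it is shared-by-target but not
shared-by-reference. Carrier frequencies are averaged across the two
families (never pooled, so a large family cannot dominate), and mean copy
numbers are averaged only over families that have at least one carrier.
Reports keep rows with non-positive frequency difference; plotting
filters are left downstream.

```{r host-example}
cmp <- host_compare(sharing, sim$meta, "Fam1", "Fam2", "vertebrate")
cmp
screen <- host_shared_orthogroups(counts, sim$meta, "Fam1", "Fam2",
                                  "vertebrate", "insect")
head(screen[, 1:5])
```

## What the synthetic generator emulates

`simulate_dataset()` plants the structure the analyses are designed to
detect, and its defaults are the package's reference study conditions:

* 4 families × 3 lineages × 4 genomes (48 genomes);
* 5 universal core orthogroups in every genome — the analog of the few
  widely distributed core proteins;
* per-family core pools of 250 orthogroups, each retained independently by
  each member genome with probability 0.8. Pools are drawn from a common
  universe of `core_universe_factor` (40) × 250 orthogroups, so any two
  families overlap by chance in roughly 2.5% of their pools. This
  background homology is what gives real virus families their nonzero
  baseline sharing; with it, baseline interfamilial $S$ sits near 0.03, an
  order of magnitude below intrafamilial values, as observed in real
  gene-content networks;
* 100 lineage-private orthogroups carried by every genome of the lineage;
* two cross-family host-gene pools of 30 orthogroups (retention 0.7),
  host types assigned at the lineage level so that each host type spans
  two families — mirroring the family-pair comparative design;
* Poisson-mean 70 genome-private singletons, and per-present-gene copy
  numbers $1 + \mathrm{Poisson}(0.1)$ — the simplest model that produces
  the multi-copy families the copy-number screen averages over, a
  stand-in rather than a biological claim.

Together these give ~400 proteins per genome with a large
family/lineage-specific majority, dozens of host-associated genes and
~70 singletons — realistic scales for giant-virus genomes. The tree is a
nested fan-out with exponential branch lengths whose means grow with depth
(0.02/0.1/0.3 substitutions per site per level); it respects the
family/lineage nesting but is not calibrated to any real clock.

What the generator does *not* emulate: sequence-level homology noise
(orthogroup inference errors), lateral transfer between specific lineages,
genome-size correlation with host, multi-host viruses, or unbalanced
family sizes. Passing tests therefore demonstrate the pipeline's
correctness and its ability to recover planted structure at realistic
scales — not that real data will be as clean.

Orthogroups that end up with fewer than two member proteins are demoted to
singletons, matching the upstream clustering convention. Generation is
fully reproducible from a single seed, which is also embedded as a `#`
header comment in every TSV the generator writes (the newick format offers
no comment field that survives round-tripping, so the tree file carries
none).

## Problem sizes used in validation

The package's own test suite validates against brute-force oracles on
hundreds of small random fixtures (3–8 taxa, 5–18 orthogroups), recovers
planted structure at the 48-genome reference conditions over 20 seeds, and
calibrates the rank test on 1,000 simulated null datasets of 12 genomes.
These sizes were chosen to exercise every code path at full statistical
resolution while keeping the whole suite comfortably fast; the pipeline
itself scales to hundreds of genomes and thousands of orthogroups without
any special handling (the sharing computation is a dense cross-product,
and MCL iterates a dense matrix of the network's size).

## Known limitations

* **The rank test is anticonservative on all-pairs designs.** Feeding the
  Mann–Whitney–Wilcoxon test every cross-family genome pair means pair
  values that share a genome are positively correlated (a genome with a
  large retained repertoire raises all of its pairs), while the
  permutation null assumes exchangeable values. On 1,000 synthetic null
  datasets the package's own acceptance check measures a rejection rate
  near 8–9% at nominal $\alpha = 0.05$. The test statistic and its exact
  distribution are verified against closed-form enumeration and
  `wilcox.test`; the miscalibration is a property of the comparative
  design itself, worth remembering when interpreting borderline p values.
  Removing the per-genome heterogeneity from the null collapses all pair
  values into ties instead (rejection 0%), so the effect is intrinsic, not
  a tuning artifact.
* Host types are single-valued per virus; multi-host viruses are outside
  the data model.
* The screen's set logic is sharp (shared iff ≥ 1 carrier in each
  family): one spurious carrier flips an orthogroup's status. Real
  analyses may want to inspect carrier counts in the report rather than
  rely on the binary classification alone.
* Virus identifiers may not contain `|`, since members of a groups file
  are split on their first `|`.
* MCL granularity interacts with network density: on denser or noisier
  networks than the reference conditions, inflation 1.5 can return
  coarser clusters than the planted partition. The inflation parameter is
  exposed everywhere for exactly this reason.
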
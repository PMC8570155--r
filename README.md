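# ncldvnet

Gene-content analysis of giant-virus (NCLDV, phylum *Nucleocytoviricota*)
genomes for comparative genomicists who have an orthogroup catalog and want
to know what the gene repertoires — rather than a handful of core genes —
say about relatedness and host association.

From an OrthoMCL-style groups file, a genome metadata table and optionally
a core-gene newick tree, the package:

* computes the normalized **gene-sharing level** between taxa $i, j$
  (genomes or family pangenomes),

  $$S_{ij} = \frac{U_{ij}}{\sqrt{T_i\,T_j}},$$

  where $U_{ij}$ counts orthogroups present in both taxa and $T_i$ counts
  orthogroups of $i$ shared with at least one other taxon — the
  geometric-mean normalization keeps unequal repertoire sizes comparable;
* builds weighted **gene-sharing networks** (Cytoscape-importable edge
  tables) and clusters them with a from-scratch **Markov Clustering**
  implementation (inflation 1.5 by default);
* reports **intrafamilial genomic variation** (between-lineage SDs of
  protein and singleton counts, mean between-lineage patristic distance)
  against **Shannon host-supergroup diversity**
  $D = -\sum_j p_j \ln p_j$;
* tests whether viruses from two families share more genes when they
  infect **similar host types** (one-sided Mann–Whitney–Wilcoxon with
  exact tie-aware p values) and screens for the **orthogroups shared by a
  target host type** but not a reference host type, with carrier
  frequencies and mean copy numbers averaged across the two families;
* ships a **synthetic-data generator** with planted family/lineage/host
  structure and a deterministic **pipeline driver** with a checksummed
  manifest.

## Worked example

Simulate a 48-genome dataset at the package's reference conditions
(4 families x 3 lineages x 4 genomes, with two cross-family host-gene
pools planted), then run the main analyses:

```r
library(ncldvnet)

sim     <- simulate_dataset(simulation_params(seed = 1))
counts  <- build_count_matrix(sim$catalog, sim$meta)
sharing <- compute_sharing(counts)
sharing
#> Gene-sharing matrix (genome level)
#>   taxa: 48
#>   S range: 0.0151 - 0.8897 (mean 0.1728)

mcl_cluster(build_network(sharing, sim$meta))
#> MCL clustering (inflation 1.5): 4 cluster(s), 48 node(s), converged in 23 iterations
#>   cluster sizes: 12 12 12 12
```

The four recovered clusters are exactly the four planted families: the
within-family sharing (S around 0.6–0.9) dominates the chance background
between families (S around 0.03). Do similar-host virus pairs across two
families share more genes than dissimilar-host pairs?

```r
host_compare(sharing, sim$meta, "Fam1", "Fam2", "vertebrate")
#> Gene sharing, Fam1 vs Fam2, host type: vertebrate
#>   similar-host pairs:  n = 64
#>   dissimilar-host pairs: n = 64
#>   one-sided MWW (normal): U = 4096, p = 8.558e-23
```

Every similar-host pair outranks every dissimilar-host pair (U equals
n1*n2), as expected with a planted 30-gene vertebrate pool. Which
orthogroups carry that signal?

```r
scr <- host_shared_orthogroups(counts, sim$meta, "Fam1", "Fam2",
                               "vertebrate", "insect")
head(scr[, 1:5], 3)
#>   orthogroup_id freq_target freq_reference freq_diff mean_copy_number
#> 1       OG10016      0.8750              0    0.8750         1.062500
#> 2       OG10018      0.8750              0    0.8750         1.000000
#> 3       OG10008      0.8125              0    0.8125         1.071429
```

The 30 reported orthogroups are precisely the planted vertebrate pool:
each is carried by most vertebrate-infecting viruses of both families
(`freq_target`), by no insect-infecting virus pair (`freq_reference` 0),
at roughly single copy per carrier.

Real data enters through `read_orthogroups()`, `read_genome_metadata()`,
`read_core_tree()` and friends; `run_pipeline()` (or the
`inst/cli/ncldvnet.R` script) runs everything end to end from a YAML
config and writes TSV artifacts plus a checksummed manifest.

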
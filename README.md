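# iinet: interface-interaction networks in R

Protein-protein interaction (PPI) networks record *that* two proteins
bind, but not *where*. A protein presents several binding interfaces, and
whether two of its partners engage the same surface (competition) or
separate surfaces (possible co-assembly) decides how complexes form and
how a network responds to a surface mutation or a binding inhibitor. An
**interface-interaction network (IIN)** resolves this: its nodes are
individual binding interfaces (`PROTEIN.index`, e.g. `ACT1.2`) and its
edges are interface-interface binding interactions. Every PPI edge with
*m* binding modes expands into *m* IIN edges, so the IIN refines its
parent PPI and projects back onto it uniquely.

`iinet` is for systems biologists who curate binding-interface evidence
(crystal structures, truncation/mutation biochemistry, peptide-domain
screens) and want to turn it into a quantitative network object. The
package covers the full workflow:

- **Data model** — S4 classes for curated PPIs (`PPINetwork`, with
  support classes from `assigned` down to `removed`), per-protein
  interface-overlap matrices (`OverlapMatrix`: symmetric 0/1 tables over
  partner-occurrences, diagonal ignored), and the derived `IIN` with
  domain-class and evidence-grade annotation.
- **Construction** — `partitionInterfaces()` consolidates an overlap
  matrix into interfaces (connected components of the shares-a-surface
  relation, with non-transitive components detected and reported),
  `buildIIN()` expands assigned PPI edges mode-by-mode,
  `projectToPPI()` inverts the construction, and `knockoutReport()`
  predicts the fallout of removing one interface, including
  alternate-route detection through same-class interfaces.
- **Topology statistics** — degree distributions with the
  single-partner self-loop convention, local/global clustering over
  distinct triplets, module (connected fragment) size distributions with
  a >=-type cumulative, and exact hypergeometric enrichment
  (`hypergeomTail()`).
- **Motifs** — an exact census of connected 4-node induced subgraphs
  into the six mutually exclusive classes (hub, chain, flag, square, and
  the 5- and 6-edge architectures).
- **Null models** — Maslov-Sneppen degree-preserving edge swaps with
  frozen self-loops (`maslovSneppen()`), and `nullEnsemble()` for
  empirical tail p-values of any statistic over >=1000 randomizations.
- **Heavy-tail fits** — discrete power-law maximum likelihood
  p(x) = x^-gamma / zeta(gamma, x_min), KS-minimizing x_min selection,
  and the semiparametric bootstrap goodness-of-fit p-value
  (`fitPowerLaw()`, `plGofPValue()`).
- **Structures** — inter-chain interface extraction from PDB/mmCIF files
  at a heavy-atom distance cutoff (default 4 A, >=3 contacting residues
  per side, cofactors excluded) and partner-pair overlap tables at
  residue or atom level (`extractInterfaces()`,
  `interfaceOverlapTable()`).
- **Synthetic ground truth** — `generateGroundTruth()` samples PPIs with
  heavy-tailed degrees, partitions partners into interfaces with a
  tunable sharing propensity, and returns the exact IIN its bookkeeping
  implies, so every pipeline stage is testable end to end;
  `toyStructurePDB()` writes toy complexes with contacts placed at exact
  distances.
- **I/O and CLI** — TSV edge lists and overlap-matrix files, SIF and
  GraphML export, and an `iinet` command-line tool
  (`inst/cli/iinet.R`) with subcommands `build-iin`, `stats`, `motifs`,
  `randomize`, `plfit`, `pdb-interfaces`, `enrich`, and `synth`.

## Worked example

```r
library(iinet)

## a curated self-consistent instance with known ground truth
gt <- generateGroundTruth(syntheticSpec(n_proteins = 56, seed = 42))
iin <- buildIIN(gt$ppi, gt$matrices, gt$annotations)
iin
#> IIN with 213 interfaces on 56 proteins and 235 interface-interface edges

degreeDistribution(asIgraph(gt$ppi))$mean_degree
#> [1] 7.446429
degreeDistribution(iin)$mean_degree
#> [1] 2.201878
clusteringCoefficients(iin)$c_local_mean
#> [1] 0

motifFractions(motifCensus4(iin))
#>         hub       chain        flag      square    diamond5     clique6
#> 0.409433962 0.588301887 0.000000000 0.002264151 0.000000000 0.000000000

fitPowerLaw(degreeDistribution(iin)$degrees)
#> Discrete power-law fit: x_min = 4, gamma = 3.627, KS = 0.0363, n_tail = 35
```

Going from the PPI to its IIN the mean degree drops from ~7.4 to ~2.2:
the same interactions are spread over ~3.5 interfaces per protein, most
interfaces bind a single partner, and clustering collapses to zero --
two interfaces that bind each other rarely share a third partner. The
motif census shows the sparse, chain/hub-dominated local structure, and
the interface degree distribution is consistent with a discrete power
law. Compare any observed statistic against degree-preserving
randomizations with:

```r
ens <- nullEnsemble(iin,
  list(c_local = function(g) clusteringCoefficients(g)$c_local_mean),
  n_samples = 1000, seed = 7)
ens$c_local
#> NullEnsemble 'c_local': observed 0, null 0.01729 +/- 0.01177 (n = 1000)
#>   p = 0.026 (less)
```

The observed zero clustering sits in the lower tail of the randomized
ensemble: interfaces that bind each other avoid sharing partners far
more than degree structure alone predicts.

A knockout query names every edge lost with an interface and whether the
orphaned partners can reroute through an interface of the same domain
class (say, an alternate SH3 domain):

```r
hub <- iinNodes(iin)$id[which.max(degreeDistribution(iin)$degrees)]
rep <- knockoutReport(iin, hub)
nrow(rep$removed_edges); table(rep$orphans$alternate_route)
#> [1] 12
#> FALSE  TRUE
#>     5     7
```

Here the top hub interface carries 12 interactions; 7 of the 12 orphaned
partners retain a route to an interface of the hub's domain class, so
the predicted phenotype of this knockout is blunted by redundancy.

The enrichment helper answers questions like "how surprising is it that
8 of 9 proteins in a subset carry a trait found in 22 of 56 proteins?":

```r
hypergeomTail(population = 56, positives = 22, draws = 9, threshold = 8)
#> [1] 0.001500745     # ~0.15%
```

## Command line

```sh
Rscript inst/cli/iinet.R enrich -N 56 -K 22 -n 9 -x 8
Rscript inst/cli/iinet.R synth --seed 7 --n 20 --out-prefix demo
Rscript inst/cli/iinet.R build-iin --ppi demo_ppi.tsv \
    --matrices "$(ls demo_overlap_*.tsv | paste -sd,)" --out demo_iin.tsv
Rscript inst/cli/iinet.R stats --graph demo_iin.tsv --kind iin
```

Logs go to stderr, results to stdout or declared output files; every
stochastic subcommand requires a `--seed`.
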
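---
title: "Building and analyzing interface-interaction networks"
author: "iinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and analyzing interface-interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iinet)
```

## The model

A curated protein-protein interaction (PPI) network carries one node per
protein and one edge per direct physical interaction, each edge graded by
a *support class*: `assigned` (both interfaces identified),
`assigned_added` (assigned, added from literature beyond the interaction
databases), `multi_study_unassigned`, `single_ref_unassigned`, and
`removed` (suspected indirect, or shown not to bind). Only the assigned
subset carries interface information; the rest stays in the data model so
curation decisions remain auditable, but never enters derived networks.

Per protein, the interface bookkeeping is a symmetric 0/1 *overlap
matrix* over its partner-occurrences: entry 1 means the two partners
engage the same surface, 0 means separate surfaces; diagonal entries are
undefined. A partner appears once per *binding mode* — a protein pair may
bind through several distinct interface pairings — and a self-binding
protein appears among its own partners, with one occurrence (same surface
on both copies) or two (two distinct surfaces).

The *interface-interaction network* (IIN) follows mechanically:
interfaces are the connected components of the "same surface" relation,
indexed per protein in order of first occurrence (`ACT1.0`, `ACT1.1`,
...), and every assigned PPI edge contributes one IIN edge per binding
mode, linking the interface containing each side's occurrence of that
mode. Consequently `|IIN edges| = sum of n_modes` over assigned PPI
edges, and projecting IIN edges back to protein pairs recovers the
assigned PPI exactly — the IIN uniquely defines its parent.

Two modeling subtleties deserve their own rules:

- **Non-transitive overlap.** A matrix can state that C's surface
  overlaps both A's and B's while A and B do not overlap (C binds across
  two distinct sites). No simple interface partition represents this;
  biologically it is resolved by splitting C's partner-side interface.
  Automatic splitting would invent interfaces the curator never asserted,
  so `partitionInterfaces()` defaults to `warn_merge`: the component is
  kept whole and a diagnostic names an offending occurrence triple;
  `policy = "error"` rejects the matrix instead.
- **Mode pairing.** When both proteins of a multi-mode edge have several
  interfaces, the pairing of occurrences is by declared mode label
  (`PARTNER@MODE`), never positional. Bare repeated labels are refused at
  parse time: silent positional pairing is exactly the kind of curation
  error the matrix format exists to prevent.

## Statistics

*Degrees.* A self-loop counts as one partner (a self-binding interface
has one more partner: itself), so degrees equal physical partner counts
rather than the graph-theoretic loop-degree 2.

*Clustering.* `C(i) = N_closed(i) / [k(i)(k(i)-1)/2]` with self-loops
ignored; nodes with `k < 2` have no partner pairs and are excluded from
the mean by default (`include_low_degree = TRUE` counts them as zero —
for sparse IINs both conventions give the same near-zero answer). The
global coefficient is computed over distinct 3-node sets,
`N_triangle / (N_triangle + N_open)`, so one triangle is one closed
triplet. This differs from the common transitivity ratio
`3 N_triangle / (paths of length 2)`; we flag this as an interpretation
of set-based triplet counting and keep it consistent between observed and
randomized networks, which is what the comparisons need.

*Motifs.* The census enumerates every 4-node subset whose induced
subgraph is connected and classifies it into exactly one of six classes:
3 edges — hub (star) or chain (path); 4 edges — square (chordless
4-cycle) or flag (triangle plus pendant edge); then the 5-edge and 6-edge
architectures (our names `diamond5`, `clique6`; only the first four have
established names in this context). Classification is on induced
subgraphs, which is what makes the classes mutually exclusive.
Enumeration is exact — no sampling — via igraph's subgraph machinery,
with an independent neighborhood-expansion enumerator
(`method = "enumerate"`) kept in the package; the test suite requires
both to agree with a naive all-`C(n,4)`-subsets oracle.

*Null ensembles.* Degree-preserving randomization follows the
edge-swapping Monte Carlo scheme: pick two nodes, one neighbor of each,
swap the partners, reject the move if a produced edge already exists,
would coincide with the other produced edge, or would create a new
self-loop. Pre-existing self-loops are frozen; together with the
rejection rules this keeps the degree multiset (under the self-loop = 1
convention) exactly conserved, which the suite asserts on every sample.
Each ensemble sample restarts a fresh chain from the observed network and
runs to `10 x |E|` accepted swaps by default — the chain length is a
package choice (mixing is empirically ample at this length; doubling it
does not move ensemble summaries), made configurable because no standard
value exists. Empirical p-values are `exceed_count / n_samples` in the
direction of the observed deviation, reported as the bound
`< 1/n_samples` at zero exceedances.

*Discrete power laws.* The tail model is `p(x) = x^-gamma /
zeta(gamma, x_min)` on integers `x >= x_min`, with the Hurwitz zeta
normalizer evaluated by direct summation plus an Euler-Maclaurin tail
correction (absolute accuracy ~1e-12; Bernoulli terms through `B_12`).
`gamma` is fit by 1-D likelihood maximization (tolerance 1e-6), `x_min`
by scanning distinct observed values and minimizing the KS distance
between tail empirical and fitted CDFs, ties toward the smaller `x_min`
(the larger tail). Zero values — isolated nodes — are excluded: the model
lives on `x >= 1`. The goodness-of-fit p-value is the semiparametric
bootstrap: replicates resample the below-`x_min` data empirically, draw
the tail from the fitted law, re-run the full `x_min` scan, and compare
KS distances; small p-values reject the power-law hypothesis.

Two honest caveats, both visible in the test suite. First, min-KS
`x_min` selection overshoots: on data with a planted tail start it never
dips below the true `x_min` but lands above it in roughly a quarter of
replicates (the exact value is still the modal outcome). Second, the
free `x_min` lets light-tailed data escape to a short far tail where a
steep power law fits locally, so the bootstrap test has little power
against, e.g., geometric alternatives at moderate sample sizes; it
decisively rejects flat alternatives. Conclusions about "consistent with
a power law" should be read with both points in mind.

*Enrichment.* `hypergeomTail()` sums exact log-space hypergeometric
terms for `P(X >= x)` — the "8 of 9 draws carry a trait present in 22 of
56" style of question.

## Structures

`extractInterfaces()` finds inter-chain interfaces in a PDB or mmCIF
file: heavy-atom pairs within the cutoff (default 4 Å), first model
only, highest-occupancy alternate locations, waters/ions/non-polymer
heteroatoms excluded but polymer-modified residues (selenomethionine and
kin) retained. An interface is kept only when each side contributes at
least 3 contacting residues — we read "at least 3 residues contacted" as
per-side, the stricter interpretation, and make it configurable.
Residues are identified by author numbering plus insertion code; mapping
to gene-sequence coordinates is deliberately out of scope. The deposited
asymmetric unit is analyzed as is, and crystallographic copies count as
distinct subunits. `interfaceOverlapTable()` then asks, for each subunit
and each pair of its partners, how many interface residues (or atoms)
the two interfaces share, and pools the pairs into 0 / exactly-1 / >1
bins — the quantitative basis for allowing a residue or two of overlap
before calling two interfaces shared. Published tables of this kind for
large complexes depend on the assembly and chain set analyzed, so
exact-percentage reproduction is approximate by nature; the suite pins
the binning down with toy complexes whose overlap is exact by
construction.

The mmCIF reader is a minimal `_atom_site` loop parser written for this
package (no installed R dependency reads mmCIF); PDB parsing goes
through `bio3d`.

## The synthetic generator

`generateGroundTruth()` exists so that every stage has a ground truth to
round-trip against, at the scale of a curated endocytosis-type module.
Defaults are calibrated once to that setting and not revisited:

- 56 proteins; PPI degrees drawn from a discrete power law on
  `k >= 4` capped at 55, exponent 3.2 — solved so the expected mean
  degree is 6.4. (A printed fitted exponent near 2.4 and a mean degree of
  6.4 cannot both hold for a pure zeta tail; we match the mean, which the
  downstream statistics are sensitive to.)
- sharing propensity 0.62 — the probability that a new partner occurrence
  joins an existing interface — solved so proteins average ~3.5
  interfaces; the induced IIN mean degree lands near 2.1.
- partner occurrences join interfaces *preferentially* (probability
  proportional to current occupancy). Real hub proteins split unevenly —
  one surface keeps most partners — and preferential joining reproduces
  that heavy-tailed interface-degree structure; uniform joining is
  available for comparison.
- second binding modes on 18/186 of edges, a third on 2/18 of those;
  self-interactions on 5% of proteins, half of them via two distinct
  surfaces; unassigned and removed edges added around the assigned core
  at curated-network proportions so exclusion logic is always exercised.
- occurrences of the same partner never share an interface (distinct
  modes engage distinct surfaces by definition), which also guarantees
  the built IIN never collapses two modes onto one interface pair.

What the generator does *not* emulate: real domain-type structure
(domain classes are sampled uniformly, so class-segregated IIN modules
do not emerge), correlated evidence grades, protein length effects, and
any particular network's exact degree sequence. Tests passing on
synthetic data therefore validate the *machinery* — construction,
statistics, conservation laws, estimator calibration — not biological
claims about any real network; and null-ensemble baselines computed on
synthetic stand-ins need not match values published for a specific
curated network, because those are functions of its exact degree
sequence.

`toyStructurePDB()` writes minimal multi-chain PDB files where requested
residue pairs sit at exact distances (two carbon atoms per residue, CA
and CB, so residue-level and atom-level overlap can be designed
independently); geometric contradictions are rejected. It makes no
attempt at biophysical realism.

## Numerical and degenerate-input choices

- Hurwitz zeta: series + Euler-Maclaurin, `s > 1`, accuracy ~1e-12.
- Power-law sampler: exact inverse CDF through a cumulative table, with
  bisection on the exact zeta survival for draws beyond the table.
- A tail with no variation (`all(x == x_min)`) drives `gamma` to the
  optimization bound (20) and is flagged `degenerate` rather than
  reported as a fit.
- `c_global` of a graph with no connected triplets is defined as 0.
- Empty IINs (no assigned edges) are valid objects and project to empty
  edge lists.
- The swap chain errors on graphs with fewer than two swappable
  (non-loop) edges, and a safety cap on trial moves turns a
  non-rewirable topology into an error rather than a hang.
- All stochastic entry points require an explicit seed; nothing reads
  the global RNG state silently, and fixed seeds make every generator
  and ensemble bit-reproducible.

## Problem sizes used by the suite

The checked-in tests and acceptance battery run at deliberately modest
scale, chosen as the smallest sizes at which each property is sharply
testable: round trips over 100 seeded instances of 10-12 proteins,
oracle comparisons on graphs of up to 14 nodes, curated-scale runs at 56
proteins, null ensembles of 1000 samples, power-law recovery at 1e5
samples, and goodness-of-fit calibration over 200 replicates of 100
samples with 100 bootstrap draws each.

## Known limitations

- Interfaces are inputs: the package consolidates curated overlap
  assertions but never infers interfaces from homology, docking, or
  sequence motifs.
- Non-transitive overlap components are reported, not auto-split.
- The goodness-of-fit test's weakness against light-tailed alternatives
  under free `x_min` (above).
- mmCIF support covers the `_atom_site` loop (coordinates, occupancy,
  alternate locations, models); exotic quoted-token layouts in that loop
  are not handled.
- Biological-assembly generation is out of scope; structures are
  analyzed as deposited.
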
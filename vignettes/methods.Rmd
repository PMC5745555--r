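---
title: "Synteny-based orthology for multicopy gene families: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synteny-based orthology for multicopy gene families: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntorth)
```

## The problem

Multicopy gene families such as tRNAs, rRNAs, snRNAs and Y RNAs evolve under
*concerted evolution*: homologous recombination and gene conversion keep
paralogous copies effectively identical in sequence over long evolutionary
times. Sequence similarity therefore carries almost no information about
which copies in two genomes are orthologs (related by speciation) and which
are paralogs (related by duplication). What does remain informative is
*synteny* — the conservation of a copy's genomic neighbourhood. If a unique
genomic region flanks a copy in one species and the orthologous unique
region flanks a copy in another species, the two copies occupy the
orthologous locus.

`syntorth` turns this idea into a pipeline: unique blocks of a genome-wide
multiple alignment act as synteny anchors; elements sharing flanking anchors
form candidate co-ortholog clusters; within clusters, sequence similarity and
genomic order refine the clusters into ortholog groups; and the groups are
mapped onto a species tree by parsimony to count insertions, deletions,
tandem duplications, singletons, missing data, pseudogenes and remolding
events.

## Anchors

An alignment block can serve as an anchor only if it marks a unique region:
blocks that overlap an element of interest (multicopy elements seed spurious
alignments) or overlap another block (ambiguous placement) are discarded, in
all species, as are blocks below a user-chosen score threshold
(`min_maf_score`, default 0 — keep everything that is scored). All
coordinates are 0-based and half-open internally; MAF minus-strand rows are
converted to forward-strand intervals at parse time, so a single convention
holds everywhere. Abutting intervals do not overlap under this convention.

For each element, the *tight anchors* are the nearest retained blocks
upstream and downstream in that element's own genome; either side may be
absent near chromosome ends or in unaligned regions. Anchor orthology is
taken from block membership: two rows of one retained block are orthologous
regions by construction of the genome alignment.

## Clusters and joining

Elements with the identical (upstream, downstream) anchor pair are
co-orthologous candidates and form the initial clusters. Alignment noise —
anchor rows missing in some species — splits true clusters: a species that
lost the row of its left anchor acquires the next surviving block as its
anchor and lands in a different cluster. Joining repairs this.

The conditions under which two clusters may merge follow the logic of
order-preserving synteny: (1) members of the two clusters must not
interleave, with a consistent left/right orientation across species; (2) no
element of a third cluster may lie between them; (3) the merged span must
stay below `max_extent` (default 50 kb) in every species, and the gap
between the outermost element boundaries of the two clusters must not
exceed `max_anchor_distance` (default 5 kb). Both limits are exposed to the
user; the defaults suit gene-sized elements at mammalian anchor densities.

Which pairs are *candidates* is decided on the anchor scale rather than the
base-pair scale: blocks keep their input (reference-genome) order, a cluster
occupies the open interval between the ranks of its upstream and downstream
anchor sets, and two clusters are candidates when their rank intervals
overlap on a common species and chromosome. Two clusters separated by a
shared facing anchor have touching, non-overlapping intervals and are never
candidates; a cluster whose anchors were lost in its own species has a wide
interval that covers the clusters it fragmented from. This rank-based
trigger is robust to heavy anchor loss, where no single genome may retain
both boundary blocks of a fragment.

Eligible pairs are merged *component-wise*: all pairwise-eligible merges in
a scan are collected, connected components of the eligibility graph are
unified at once, and scanning repeats to a fixed point. Pairwise greedy
merging is order-dependent — an early merge can tighten a cluster's anchor
projection so that a fragment that was compatible with the original cluster
can no longer join — while component union is order-independent, and any
over-joining is corrected downstream by the similarity and order analysis.

Two modes differ in which species are checked. The *relaxed* mode (the
default, and the mode we recommend) checks only species that have a member
in either cluster. The *strict* mode additionally requires, in species with
members in neither cluster, that no foreign element lies inside the joint
anchor-projected region and that this region is not oversized. Strict
joining therefore never merges more than relaxed joining.

## Orthology within a cluster

Within a cluster, a similarity graph is built: vertices are members, and an
edge joins two members whose global-alignment identity reaches the
`similarity_threshold` (default 0.80, the value that works well for tRNA
conservation levels; families with different conservation need a different
setting). Identity is computed from a Needleman–Wunsch alignment with match
+1, mismatch −1, gap −1; the denominator is the full alignment length, so
length differences penalize both sequences symmetrically. Among equal-score
alignments the one with the most identical columns, then the shortest, is
used — an additive lexicographic objective, so the value is deterministic.
The comparison is non-strict (identity ≥ threshold draws the edge).

A valid orthology relation must be a *cograph* — no four vertices may induce
a P4 path. Thresholding real similarities sometimes violates this, and the
graph is repaired with the minimum number of edge insertions and deletions.
Minimum cograph editing is NP-hard, but the clusters met in practice are
small: graphs up to `exact_limit = 10` vertices are solved exactly by an
iterative-deepening branch-and-bound that branches over the six vertex
pairs of an induced P4. Larger graphs are decomposed into connected
components (a P4 never spans components) and components up to 63 vertices
fall back to a greedy heuristic that repeatedly applies the single edge
flip destroying the most induced P4s. Ties everywhere prefer inserting an
edge over deleting one, then the lexicographically smallest vertex pair;
inserted edges carry the threshold value as a conservative weight. A
component beyond 63 vertices is left unedited with a warning — in data that
large the family is better analysed at a higher threshold.

Orthologous elements must also appear in a compatible genomic order. For
every species pair, the cluster's element orders are aligned with a
Needleman–Wunsch variant in which an element of one order may match a *run*
of consecutive elements of the other (a tandem-duplication match). Matches
are restricted to edges of the edited graph, matched pairs score their
identity, gaps cost nothing, and opening a run costs `run_open = 0.05` —
just enough that a run never forms when a one-to-one matching scores
equally. Crossing matches are excluded by construction, which is exactly
why an alignment formulation is used: it removes orthology edges that
contradict the genomic order. A run of length *k* records *k* − 1 tandem
duplications in the run's species.

Ortholog groups are the connected components of the retained cross-species
matches. Elements that retained no match are grouped per species within
their edited-graph component: a component confined to one species
(in-paralogs) stays together, while a component whose matches were all
removed as crossings falls apart into per-species groups. Same-species
similarity edges never bridge two alignment-separated groups — under
concerted evolution raw similarity cannot discriminate loci, so the order
evidence wins. Per-leaf duplication counts aggregate over partner species
by taking the maximum, so one tandem event observed against several
partners is counted once; a group confined to a single species contributes
its copy number minus one.

## Events on the species tree

Let σ(C) be the species carrying group *C* and ℓ their last common ancestor
in the rooted species tree. By parsimony, *C* first appears (*insertion*)
on the edge ancestral to ℓ; a group spanning the root is an insertion
before the root. *Deletions* are counted on the edges ancestral to the
maximal subtrees below ℓ containing no species of σ(C); on a fully resolved
tree such an edge can never lead to a child of ℓ, because both child
subtrees of ℓ contain σ-species by the definition of the LCA. Under
polytomies child-of-ℓ deletions are emitted when forced.

A species scored as a deletion is reclassified as *missing data* when
neither flanking anchor block of the group's cluster has an alignment row
for it: without any alignment coverage, an absent element cannot be
distinguished from an unaligned region. This coverage-based rule is the
package's operationalization of the missing-data category; it only ever
moves leaves from the deletion column to the missing column and never moves
the insertion edge. Singleton groups are tallied at their leaf and also
appear as leaf-edge insertions in the tree output. Pseudogenes participate
in clustering and orthology but are tallied separately per species, and
they are excluded from remolding reports unless requested.

*Remolding* — a type switch such as a tRNA anticodon change — is reported
for any within-cluster pair with distinct type labels but identity at or
above the threshold; the converse (same type, identity below threshold) is
reported as a divergent pair. Singleton clusters can contribute neither.

## The benchmark generator

`generate_benchmark()` builds the study conditions used throughout the
package's validation: six species on a fixed balanced tree, genomes linked
by colinear anchors (default 10,000; 100 bases each, 1,000-base gaps), and
100 elements of three types placed in the gaps. Sequences are 75-nt
per-type templates; copies within a group are identical — the signature of
concerted evolution — and templates are redrawn until all between-type
identities fall below 0.6, so the 0.8 orthology threshold separates types
decisively. Each group occupies its own inter-anchor gap and a uniform
random nonempty species subset (`placement = "homologous-subset"`; the
`homologous-all` and `random` modes cover the boundary cases). A fraction
`dup_fraction` (default 0.1) of groups receives a tandem copy adjacent to
one of its members, and about 10% of copies sit on the minus strand so that
strand-aware sequence extraction is exercised.

Noise imitates incomplete genome alignments: with probability
`anchor_loss`, each anchor *row* (block × species) is deleted
independently — per-species loss leaves partial coverage and so exercises
the missing-data classification; a `per-block` mode removes whole blocks
instead. All placement draws precede the noise draws, so runs with the same
seed and different `anchor_loss` share their ground truth and can be
compared pairwise. Ground-truth event counts are the parsimony placements
of the true groups, computed with the same tree operations the pipeline
uses — the truth is defined by the generating σ sets, and parsimony is the
agreed reading of them.

What the generator does *not* emulate: sequence divergence along the tree
(copies are identical, as concerted evolution idealizes), genome
rearrangements between anchors, pseudogenes, and assembly artefacts beyond
anchor loss. Passing the benchmark therefore demonstrates the synteny and
order logic, not robustness to rearranged or diverged real genomes.

## Validation and problem sizes

The test suite validates each computational kernel against an independent
brute-force reference: global-alignment identity against exhaustive
alignment enumeration, the duplication-aware order alignment against
enumeration of all non-crossing run-matchings (200 random instances with up
to 6 elements per side), and cograph editing against an
iterative-deepening subset enumeration (200 random graphs with up to 8
vertices), plus direct P4-freeness checks. Event placement is tested as
laws over random resolved trees with 6–12 leaves: one insertion per group
above the LCA, deletion subtrees maximal, σ-free and never at a child of
the LCA, and σ, deleted and missing leaves partitioning the leaves below
the LCA.

End-to-end behaviour is validated on the benchmark. With perfect data
(no anchor loss) the pipeline reconstructs the generating ortholog groups
exactly and every event count matches the truth; this is checked at 500
anchors (a desk-scale geometry that keeps the default test run fast) and at
the full 10,000 anchors. The noise study runs 20 paired replicates at
anchor losses of 0, 20% and 40% at the full geometry, where the expected
qualitative behaviour appears: singleton counts do not grow (fragments are
rejoined; adjacent same-type loci absorbed across lost anchors remove
singletons), inferred tandem duplications grow (joined loci with
overlapping species ranges are read as runs), and missing-data counts grow
(species losing both flanking rows can no longer be scored as deletions).
Disabling joining multiplies the total event-count error by more than an
order of magnitude, almost entirely through spurious singletons.

One directional claim deserves honesty: whether joining yields *at least
as many* interior-node insertions as no joining. In this implementation the
joining run tracks the truth closely, while the no-joining run scatters
around the truth — fragments that coincidentally share an anchor pair in
two species add spurious interior-node groups, and dispersed small groups
remove them. The sign of the difference is therefore a near-tie decided by
seed noise rather than a stable property, and the corresponding check may
fail even though joining is strictly more accurate on every error measure.
We report it as measured rather than tuning the generator toward a pass.

## Numerical and degenerate-input choices

* Identity of equal sequences short-circuits to 1 without an alignment.
* Empty similarity clusters (single members) skip graph construction.
* Clusters whose members lack type labels are skipped by remolding with a
  warning; remolding is never attempted within singleton clusters.
* `NA` MAF scores are kept at the default score threshold (absence of
  evidence is not treated as a low score).
* Elements with no anchors on either side become flagged singleton
  clusters; they can still be joined into neighbouring clusters when their
  member positions fall inside a candidate region.
* All tie-breaks (cograph edits, alignment traceback, merge components)
  are deterministic, so a seed affects only the benchmark generator.

## Limitations

The method assumes conserved gene order between tight anchors; lineages
with fast rearrangement (e.g. nematode-scale distances) erode the anchor
map and with it the power of the approach. Anchor quality bounds
everything: regions absent from the genome alignment are invisible and
surface only as missing data. Duplication counts are per-leaf lineage
totals, not a full reconciliation of the duplication history — merging
pairwise duplication alignments into a single multiple alignment with
duplications remains an open problem, and gains and losses are counted by
parsimony, not by rate models.
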
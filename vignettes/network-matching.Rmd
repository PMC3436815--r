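---
title: "Stitching fragmented genes across a de Bruijn contig graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stitching fragmented genes across a de Bruijn contig graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genestitch)
```

## The problem

De Bruijn graph assemblers break metagenomic reads into k-mers and report
maximal unbranched stretches of the k-mer graph as contigs.  When a sample
contains homologous genes from closely related organisms, the regions those
genes share behave like repeats: the graph branches at every shared
stretch, contigs end there, and a single gene ends up scattered across many
short contigs.  Gene predictors and similarity searches then perform poorly
because no contig carries a complete gene.

The assembler, however, also reports the edges it could not resolve.  This
package uses those edges: given a reference gene from a related organism,
it searches the contig graph for the chain of contigs whose concatenated
sequence is most similar to the reference — a *gene path* — and reports the
spelled sequence as a stitched, more complete gene.  Overlapping gene paths
obtained from similar references are merged into *gene graphs*, each
representing one family of homologous genes, with the highest-scoring
member path as the family's representative sequence.

## The graph model

A contig graph (`contig_graph()`) holds contigs as nodes and a directed
edge `u -> v` wherever the last `k - 1` bases of `u` equal the first
`k - 1` bases of `v`.  Spelling a path concatenates the contig sequences
and drops one copy of each junction overlap, so a path over contigs of
total length `L` with `e` edges spells `L - e * (k - 1)` bases.  Input is
accepted as GFA 1.0 (`read_gfa()`; `k` is inferred from the link overlap)
or as FASTA plus a two-column edge list (`read_edge_list()`).  Every load
validates every edge against the sequences it joins.

The graph is held in a single fixed orientation; reverse-strand genes are
handled by also aligning the reverse complement of each reference, not by
doubling the graph.  Contigs that participate in edges must be at least
`k` long so that a junction always leaves at least one non-overlap base —
the graph-side coordinate of a junction would otherwise be undefined.

## The network-matching alignment

The core computation (`align_graph()`) is an affine-gap local alignment
between *all paths of the graph* and one reference, done by dynamic
programming over the graph rather than by enumerating paths.  For contig
position `i` of contig `v` and reference position `j` three quantities are
maintained:

* `S(i, j, v)` — the best alignment ending with base `i` matched or
  mismatched against reference base `j`;
* `I(i, j, v)` — ending with reference base `j` against a gap;
* `D(i, j, v)` — ending with graph base `i` against a gap.

Within a contig these follow the usual Smith-Waterman-with-affine-gaps
recurrences: a match/mismatch move pays `+1` or `-2`, the first base of a
gap pays `-3` and each further gap base `-1` (the defaults; see
`scoring_scheme()`).  `S` takes the maximum over the three matrices at its
diagonal source and is floored at zero, which is what makes the alignment
local.  At a contig start (`i == 1`) the diagonal and deletion recurrences
instead draw from the junction cell of every predecessor contig, which is
how the alignment walks across edges without enumerating paths.

Two details of the junction treatment matter for correctness:

* **Each spelled base is scored once.**  Because an edge means the
  predecessor's suffix equals the successor's prefix, the junction cell of
  predecessor `l` is its last *non-overlap* position, `last(l) - (k - 1)`;
  the shared bases are carried by the successor's prefix.  With this
  convention the graph DP is exactly equivalent to running the linear
  aligner on the spelled sequence of the best path — a property the test
  suite checks against brute-force path enumeration.
* **Insertions need no junction case.**  An insertion consumes a reference
  base while the graph pointer stands still, so its source is always the
  same graph cell one reference column back.  Giving `I` a predecessor
  case would let an alignment slide across a junction without consuming
  the successor's first base — a free skip that breaks the equivalence
  above.  The deletion matrix `D`, which does consume graph bases, has the
  junction case.

Traceback starts from the global maximum of `S` (scanning reference
positions, then contigs in processing order, then contig positions, first
maximum wins) and follows recorded moves until it reaches a score of zero,
emitting per-column operations and the contig chain.  Ties between moves
prefer the diagonal from `S`, then from `D`, then from `I`; among
predecessors the lexicographically smallest contig id wins.  These rules
make results reproducible to the byte.

Both orientations of the reference are aligned and the better strand is
reported, ties going to `+`.  Reported coordinates are 1-based inclusive
on the forward reference; the `stitched_seq` is always on the forward
graph strand.

**Cycles.**  De Bruijn graphs may contain cycles.  Contigs are processed
in the topological order of a DAG obtained by depth-first search from
in-degree-zero contigs (smallest id first) with back-edges set aside;
back-edges still feed the diagonal recurrence, which naturally looks one
reference column back, so they cannot create same-column loops.
Back-edges do not feed the deletion junction case: a deletion sourced from
a stale column would emit an alignment whose columns no longer reproduce
its score, and the package treats score-from-columns reproducibility as an
invariant (`rescore_path()`).  Traceback additionally caps each contig's
visit count at two and warns if the cap is hit.  Gene sequences rarely
traverse cycles, so in practice these bounds are never active.

**Memory.**  The implementation stores all three score matrices plus
one move byte per cell, about 15 bytes per (graph base x reference base)
cell.  Seeded subgraphs (below) keep the graph side to a few kilobases,
so a 900 bp reference costs tens of megabytes.

## Seeding: constraining the search

Aligning every reference against the whole graph would be wasteful, since
one gene spans a tiny part of it.  `find_hits()` finds contig-vs-reference
similarity hits, either from a BLAST outfmt-6 file (kept at E-value <= 0.1,
deliberately permissive so short fragments survive) or from a bundled
seeded search (contigs sharing an 11-mer with the reference are aligned;
raw score >= 20 counts as a hit — invented defaults standing in for
E-value machinery, with the BLAST route as the fidelity path).
`build_subgraph()` then grows the reference's search space outward from
the best-hit contig over both in- and out-edges: hit-bearing contigs are
recruited at any depth and reset the hit-free counter; hit-free contigs
are recruited only up to `N = 5` consecutive hit-free layers.  The search
runs to a fixpoint, so the recruited set is independent of traversal
order.  The alignment then runs on the induced subgraph — one gene path
per reference per seeded subgraph.

`mask_intact_genes()` implements the second speed-up: predicted genes
lying wholly interior to a contig need no stitching and are cut out before
matching, the leftmost remnant keeping the contig's in-edges and the
rightmost its out-edges.  Remnants shorter than `k` cannot carry graph
structure and are dropped.  Predictions touching a contig end are exactly
the fragmented genes the method exists for, and leave the contig
untouched.  Annotations come from GFF3 or from the bundled six-frame ORF
caller (`find_orfs()`, minimum length 180 bp by default).

## Gene graphs

Raw gene paths are filtered (`filter_paths()`) by three inclusive
thresholds: alignment score >= 50, identity >= 60% (matches over all
aligned columns, gaps included), and reference coverage >= 40%.  The
identity floor is deliberately low because references may come from
distantly related organisms.

Two filtered paths merge into one gene graph (`merge_paths()`) when they
share at least one contig *and* the references they were inferred from are
at least 70% identical.  Reference-vs-reference identity is taken from the
best local alignment over both strands, with one guard: the alignment must
span at least 40% of the shorter sequence, otherwise the identity is
reported as zero.  Unrelated sequences always share some short perfect
word, and the identity of a ten-base exact match says nothing about
homology; the guard plays the role a similarity search's significance
threshold would play, and reuses the 40% coverage floor already applied to
gene paths.  Merging runs to a fixpoint with union-find over
deterministically ordered pairs, so it is transitive (A-B and B-C mergeable
implies one graph even if A and C fall below 70%) and independent of input
order.

`extend_gene_graph()` then recruits in- and out-neighbours whose best
local alignment against any member contig reaches 70% identity over at
least `k` aligned columns — the aligned-length floor prevents recruitment
on the strength of the `k - 1` junction overlap alone — repeating until no
contig can be added.  Each gene graph reports its highest-scoring member
path as representative (ties: higher identity, then smaller reference id).

## The simulator

`simulate_community()` generates the situation the method targets, so the
whole pipeline is testable without external data.  Per family, an ancestor
gene is drawn uniformly at random; each community member copies it with
substitutions at `community_divergence` (default 3%, strains or close
species) except inside a conserved core window (default `3k` bases,
divergence zero) — homologous genes really do share near-identical
stretches, and the exact shared core is what forces the de Bruijn graph to
tangle.  Each community gene also gets a reference homolog, mutated from
it at `reference_divergence` (default 15%, a related species per the
genus-to-order range).  Genes are embedded in per-member genomes with
random intergenic spacers and the genomes are compressed into a unitig
contig graph (`build_unitig_graph()`): distinct k-mers, observed
`(k+1)`-mer adjacencies, maximal unbranched stretches as contigs.  The
builder records each input's contig walk, so ground truth (true paths,
per-contig gene intervals, gene locations) is exact.  Mutations are
substitutions only by default so identity arithmetic in tests stays exact;
an indel rate is available.

What the simulator does *not* model: sequencing errors, coverage
variation, chimeric reads, and strand mixtures (genes are embedded
forward; reverse-strand handling is exercised by reverse-complementing
references in tests instead).  Passing tests on simulated tangles shows
the graph search, merging and evaluation machinery are correct; it does
not certify performance on real sequencing data, where assembler-specific
artefacts add noise the pipeline never sees here.

## Evaluation

Three metrics mirror how gene assembly quality is usually reported:

* **Gene coverage** (`gene_coverage()`): for each true gene, the fraction
  of its length covered by its best-matching assembled sequence at >= 98%
  identity; averaged over genes, unmatched genes counting zero.
* **Complete genes** (`count_complete()`): a true gene is complete when an
  assembled sequence covers >= 90% of it at >= 98% identity; each
  assembled sequence may complete at most one gene (greedy best-first
  matching, deterministic order).
* **Misassembly** (`misassembly()`): each assembled gene is aligned to the
  truth genomes; it maps cleanly if one local alignment covers >= 90% of
  it at >= 95% identity.  Otherwise it is misassembled: unmapped, or
  chimeric when two disjoint segments (>= 100 bp each) place at different
  locations.  Chimeras whose segments fall in two same-family genes are
  flagged *minor* — interleaving near-identical homologs is sometimes
  unavoidable.  The 90%/95%/100 bp operationalisation is this package's
  own (read mappers do not print their internal thresholds) and all three
  are arguments.

One known blind spot: a mosaic of two homologs that differ by only a few
percent maps to either source genome above the 95% identity floor and is
counted as cleanly mapped.  This matches how mapping-based misassembly
detection behaves in practice — such mosaics are exactly the "minor"
category — but means the reported misassembly rate is conservative for
very close homologs.

## Problem sizes and the headline run

The bundled end-to-end run (also performed by `scripts/acceptance.R`)
simulates 20 families x 2 members with 900 bp genes at k = 31 — roughly
50 kb of genome, a 400-500 contig graph — stitches against the 40
reference homologs, and evaluates against truth.  These sizes keep a full
run in minutes on one core while producing graphs tangled enough that
every gene is fragmented across ~10 contigs.  On this scenario all 40
gene paths pass the filters and every community gene is recovered by its
path to the complete-gene standard; gene coverage of the stitched output
roughly doubles the per-contig baseline.

One behaviour of the full pipeline deserves a note.  At 15% reference
divergence, the two references of a family sit right at the 70% pairwise
identity threshold, so most families' two paths merge into one gene graph,
which then reports a single representative.  The representative matches
one member at ~100% identity and the sibling member at only ~94% — below
the 98% completeness standard — so representative-level completeness
settles near one gene per family (about half the community genes), even
though path-level recovery is complete.  This is the method's intended
trade-off: merging near-identical homologs into one gene graph avoids
misassembly at the cost of not separating family members.  Both numbers
are reported by the acceptance script (`complete_gene_ratio_pct` for
representatives, `complete_gene_ratio_paths_pct` for kept paths).

## Worked example

```{r example}
truth <- simulate_community(sim_config(seed = 42, n_families = 3,
                                       gene_len = 450, intergenic_len = 100))
truth$graph

res <- stitch_genes(truth$graph, truth$reference_genes)
res
tidy(res)

ev <- evaluate_assembly(setNames(res$genes$seq, res$genes$gene_id), truth)
ev
```

## Limitations

* Nucleotide space only: no translated (protein-level) matching, so very
  distant homologs that align only as proteins will not seed paths.
* One gene path per reference per seeded subgraph; secondary local optima
  are not reported.
* Cycles are traversed through one deterministic unrolling, not
  enumerated.
* Eukaryotic intron-containing genes are out of scope.
* The internal hit search has no E-value statistics; for real data,
  precomputed BLAST tabular hits are the recommended input.
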
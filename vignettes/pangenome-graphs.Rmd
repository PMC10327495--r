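---
title: "Pangenome graphs by progressive alignment: model, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pangenome graphs by progressive alignment: model, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains what the package computes, which knobs matter,
what the bundled simulator does and does not emulate, and the design
decisions taken where several reasonable choices existed. It states no
empirical result beyond what the test suite and `scripts/acceptance.R`
compute themselves.

## The model

A *pangraph* represents a set of complete (usually circular) bacterial
genomes as paths through *pancontigs*. A pancontig is a directed block
holding a consensus sequence and, for every occurrence of the block in a
genome, the edits — substitutions, insertions, deletions, all in 0-based
half-open consensus coordinates — that reconstruct that isolate's
sequence. The block's internal alignment is a *star phylogeny*: each
member differs independently from the consensus, with no within-block
tree structure. Nucleotide-scale variation therefore lives inside
blocks, while structural variation (inversions, rearrangements, gain and
loss) lives in the graph topology; the split between the two scales is
set by the minimal block length `L_min`.

Construction approximates a multiple-genome alignment by progressive
pairwise *graph* alignment:

* a guide tree orders the merges: minimizer sketches, Jaccard
  distances, neighbour joining, then rebalancing to a depth-minimal
  binary tree that preserves the NJ leaf order (so similar genomes merge
  early and disjoint subtrees are independent work units);
* one merge step aligns all pancontig consensuses of the union graph
  all-to-all (including self-alignment, so paralogous duplications can
  merge) and scores each hit with the pseudo-energy
  `E = −ℓ + α·N_c + β·N_m`; admissible (`E < 0`) mergers are applied
  best-first, and the loop re-aligns and repeats until no admissible
  merger remains.

The energy balances compression (`−ℓ`) against graph fragmentation
(`α·N_c`, one unit per cut not already at a block end) and block
diversity (`β·N_m`). Two consequences worth internalizing: with the
default `β = 10`, no merger joins consensuses whose alignment divergence
reaches `1/β = 10 %` — the supremum of admissible divergence over
integer polymorphism counts is exactly 10 %, never attained — and with
`α = 100` short homologies cannot pay for the blocks they would create.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `alpha` | 100 | bp | cost per additional block a merger creates |
| `beta` | 10 | bp | cost per polymorphism; divergence ceiling `1/beta` |
| `len_min` | 100 | bp | minimal pancontig length; cuts nearer a block end snap to it |
| sketch `k`, `w` | 15, 10 | bp | minimizer k-mer and window for guide-tree distances |
| kernel | minimap2 `asm20` | — | consensus aligner; `asm10` for less diverged sets, `builtin` for a binary-free run |
| `max_rounds` | 64 | — | safety cap on align/merge rounds (a warning, never silent truncation) |

`N_m` counts each indel as **one** polymorphism event regardless of
length, so a single long insertion does not veto a merger the way an
equal number of substitutions would; this matches the event-counting
reading of the polymorphism term and is the package's documented choice
(the alternative — counting indel bases — would make the divergence
ceiling length-dependent).

Cut snapping: when a hit boundary falls within `len_min` of a block end,
the cut moves to the end and the alignment is extended across the
absorbed flank, which enters the fused alignment as a terminal indel
(and adds one event to `N_m`). For self-hits (a block merging with
another interval of itself), the stretch *between* the two intervals
would become its own block; candidates whose inter-interval gap is
shorter than `len_min` are refused so the floor holds there too.

## Numerical and structural choices

* **Consensus voting.** After every fusion the consensus is recomputed
  by column-wise majority over the implied alignment (consensus columns
  plus padded insertion columns). A/C/G/T vote individually; ambiguity
  codes vote only in columns with no standard base; base-vs-gap ties
  keep the base; base-vs-base ties take the lexicographically smallest
  base. All rules are order-independent, which schedule independence
  requires.
* **Conflict resolution.** Within one round, candidates are applied
  best-energy-first and a block consumed by one merger locks out later
  candidates touching it; displaced candidates are rediscovered by the
  next round's re-alignment. The paper-level method specifies the
  ranking; this greedy one-round locking is the package's concretization
  and guarantees progress (every applied merger strictly reduces total
  consensus length, which also bounds the loop).
* **Determinism and schedule independence.** Block ids are content
  hashes of their operation history, ties break lexicographically, the
  external kernel runs single-threaded, and JSON export canonicalizes
  block order and labels. Independent guide-tree jobs touch disjoint
  graphs, so any topologically valid execution order yields a
  byte-identical exported document (tested).
* **Circular genomes.** Paths carry a circular flag and a start-offset;
  alignment operates on the linearized sequence, so homology across the
  origin is cut there in every genome alike. Transitive-chain compaction
  may fuse across the wrap junction, in which case the offset absorbs
  the rotation and reconstruction stays exact.
* **Degenerate inputs.** A single genome yields a single-block graph
  (self-duplications within one genome are only discovered once a
  pairwise merge runs); an empty consensus after voting aborts the
  merger; a genome shorter than `len_min` is allowed and simply yields a
  short block.
* **Polish.** Merging never re-aligns member insertions against each
  other, which can double-count shared indels. `polish_block()` runs a
  star realignment (each member globally re-aligned to the consensus
  with affine gaps) followed by a vote, iterating while the total edit
  count drops. It is quadratic per member and intended for post-hoc
  cleanup of blocks, not for the build loop.

## The simulator and what passing tests show

`simulate_population()` evolves `n` genomes for `T` generations of
Wright–Fisher reproduction (each child copies a uniform parent). Per
child and generation, Poisson numbers of events are applied in the
order inversions, deletions, horizontal transfers, substitutions;
donors come from the parent generation. Event lengths are geometric
(defaults: inversions 5 000 bp, deletions 500 bp, transfers 5 000 bp);
substitution counts are Poisson with per-site rate `mu`, and
`mutation_rate_for_divergence()` converts a target average pairwise
divergence into `mu` using the expected pairwise coalescence time
`n·(1 − (1 − 1/n)^T)` and a Jukes–Cantor correction. Defaults follow
the structural rates of 0.01 inversions and 0.05 deletions per genome
per generation with `T = 50`; the transfer rate (default 0.05) and all
length means are free parameters, chosen at realistic bacterial scales.

Two deliberate simplifications: event segments never wrap the origin
(starts are uniform over placements that fit), which keeps one shared
coordinate origin across the population so ground truth is unambiguous;
and a horizontal transfer replaces the recipient's segment with the
donor's segment *at the same coordinates*, a homologous-replacement
reading that is exact while both lineages are syntenic and approximate
after rearrangements. The simulator tracks every genome as a tiling of
ancestral intervals plus substitution lists, so `true_pangraph()` can
build the exact graph a perfect aligner would produce: ancestor
coordinates are cut at every junction observed in any genome, because a
junction in one lineage refines the block structure of every path.
Junctions fixed in all genomes (e.g. a deletion that swept) are
invisible in the extant sequences and are compacted away by default
(`compact = FALSE` keeps them). Accuracy is then measured by pairing
block boundaries of the built and true graphs within 1 kb and reporting
displacements; pairing is greedy nearest-first by default, with an
optimal non-crossing assignment available (`method = "optimal"`) — the
two agree on well-separated boundaries, which is the regime graphs
produce.

What the simulator does **not** emulate: selection, recombination
hotspots, gene structure and annotation, insertion-sequence expansions,
GC skew, or assembly errors. Passing the accuracy tests therefore shows
that the algorithm recovers the structure its own generative model
produces at the stated divergences — not that every real-data artefact
is handled.

## Problem sizes used by the tests

The suite runs at desk scale, chosen so the full run completes in a few
minutes while still exercising every code path: round-trip exactness on
25 genomes of 15 kb; the minimal-length floor and the acceptance script
on 10 genomes of 100 kb; breakpoint accuracy on 10 genomes of 50 kb at
~1 % and ~15 % average pairwise divergence (three seeds pooled);
marginalization consistency on 20 strains of 100 kb with 20 random
pairs. Genome length matters for the marginalization comparison: the
disagreement between a marginalized and a directly built pairwise graph
is a boundary effect of order `L_min` per affected junction, so its
*fraction* of the genome scales inversely with genome length — at
100 kb it sits below 1 %, mirroring the behaviour on real multi-Mb
chromosomes.

## Known limitations

* The divergence ceiling is a hard consensus-level cutoff: datasets
  whose core divergence approaches 10 % fragment, and beyond it only a
  more sensitive kernel (the `mmseqs2` adapter slot is unimplemented)
  or relaxed `alpha`/`beta` would help.
* The builtin kernel uses unique-k-mer anchors and cannot seed
  within-sequence paralog self-hits; the minimap2 kernel covers those.
* Minimizer hashing holds k-mer codes in exact doubles, capping `k` at
  26 (defaults use 15 and 21).
* Graph JSON is self-defined (schema version 1.0) and not
  byte-compatible with other tools' formats; GFA v1 export is the
  interchange route.
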
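---
title: "Detecting bubbles, superbubbles and bubble chains in bidirected genome graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting bubbles, superbubbles and bubble chains in bidirected genome graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfabubbles)
```

## The graph model

`gfabubbles` operates on bidirected sequence graphs: each node carries a DNA
sequence (or only its length) and has a left and a right side; each edge joins
one side of one node to one side of another. This is the natural model for
GFA1 data: a link `L u + v - 3M` attaches the right side of `u` to the right
side of `v` with a 3-base overlap, meaning a walk that traverses `u` forward
continues through `v` in reverse complement. Overlap CIGARs are restricted to
exact matches (`<int>M`, or `*` read as 0): in the de Bruijn graphs this
package targets, overlaps are exactly `k - 1` matches, and silently
approximating a gapped overlap would corrupt every downstream base count, so
anything else is a parse error. Blunt (overlap-0) and overlap edges may
coexist in one graph; nothing in the algorithms distinguishes them beyond the
arithmetic.

An oriented traversal is a pair (node, direction). Entering a node on its
left side and leaving right is the "+" orientation; the reverse is "−". The
*doubled graph* over these oriented vertices is an ordinary directed graph,
and all reachability arguments below live there.

## Superbubble detection

A superbubble between a source `s` and sink `t` is a subgraph that is
directed and acyclic, in which the vertices reachable from `s` are exactly
the vertices from which `t` is reachable, and which is minimal: no interior
vertex satisfies the same conditions with `s` or with `t`.

`find_superbubble()` implements the frontier search of the average-case
linear-time algorithm of Onodera, Sadakane and Shibuya, adapted to the
doubled graph: starting from an oriented source end, repeatedly visit a
frontier vertex all of whose parents are visited and mark its children seen;
abort on a childless vertex (a tip cannot be inside a bubble), on reaching
the source node again (a cycle), or on meeting any node in both orientations
(the subgraph would not be consistently directed); succeed when exactly one
vertex remains seen-but-unvisited and the frontier holds only it. The
candidate sink is finally rejected if it links straight back to the source.

Three design points deserve a note:

* **Search starts.** Only ends with at least two children are used as
  sources. A superbubble entered through a one-child node is either
  non-minimal or discovered from the branching node inside; skipping these
  starts changes nothing in the output and avoids quadratic behavior on long
  unitig paths.
* **Canonicalization.** Every bubble is found twice, forward from its source
  and backward from its sink. A bubble is identified by its two boundary
  ends — (node, side facing into the bubble) — ordered lexicographically,
  which merges the two discoveries and makes counting well defined.
* **Nesting.** Detection over the whole graph already returns nested
  superbubbles (a superbubble nested in another is a superbubble of the full
  graph in its own right). Parent links are therefore assigned by node-set
  containment — the smallest bubble whose interior contains the child's
  interior and both its endpoint nodes — rather than by re-running detection
  inside each interior; on superbubble forests the two formulations coincide,
  and containment keeps detection single-pass. Interval-based nesting, which
  assumes a global linear order, would be incorrect on bidirected graphs and
  is not used.

Classification happens after detection: a bubble is *simple* when it has
exactly two interior nodes, each adjacent only to the source end and the sink
end, and no direct source–sink edge; it is an *insertion* bubble when one
interior branch runs in parallel with a direct source–sink edge (the
deletion allele has zero length). Insertion bubbles are counted separately
from simple bubbles rather than folded into either category, since a
two-path definition of "simple" is ambiguous about them. Both
classifications presuppose a compacted graph — on a raw k-mer graph a
two-path bubble has `k` interior nodes per branch — which is why the CLI
compacts before detecting unless `--no-compact` is given.

## The definitional oracle

`oracle_superbubbles()` is deliberately naive: for every ordered pair of
oriented ends it computes forward reachability from `s` (stopping at `t`),
backward reachability from `t` (stopping at `s`), checks set equality,
rejects subgraphs containing a node in both orientations or a directed
cycle (Kahn's algorithm on the induced subgraph), and finally applies the
minimality clause literally — a candidate dies if any other valid pair
shares its source with a sink inside it, or its sink with a source inside
it, where pairs with empty interiors participate in the filter but are never
reported. It shares no traversal code with the detector beyond the doubled
adjacency index. The central correctness property of the package is exact
set equality of detector and oracle on hundreds of seeded random graphs
(mixed blunt/overlap edges, with and without self-loops); the test suite and
the acceptance script both recompute it.

## Utility operations

**Compaction** (`bdg_compact()`) contracts every maximal linear path — each
internal connection via sides of degree one — into one node. Members entered
through their right side contribute their reverse complement; each edge's
overlap is trimmed from the successor's prefix. Merged ids concatenate
member ids with `"_"` in path order, which keeps provenance visible in
reports at the price of long ids (display methods abbreviate). A node with
two edges on the *same* side is a junction, never merged through: sequence
through it is not linear. Nodes with self-loops are likewise junctions.
A circular linear path (every side degree one around a cycle) contracts to a
single self-loop node starting at its lexicographically smallest member, so
the result is deterministic. One pass finds all maximal paths, hence
compaction is idempotent, a property the tests assert on random graphs.

**Biggest component** (`bdg_biggest_component()`) measures size in node
count (as in the graph-preparation step it supports); equal-sized components
tie-break to the one containing the smallest node id. **Neighborhood
extraction** (`bdg_neighborhood()`) is breadth-first by *node count*, not hop
radius — the intended use is carving a screenful of graph around a locus for
visualization, where a node budget maps better to what a viewer can render;
neighbors are enqueued in sorted id order so the subgraph is reproducible.
A hop-radius variant would be a straightforward alternative; node count was
chosen and is documented on the flag.

## Bubble chains

Top-level bubbles whose endpoint nodes coincide link into chains; nested
bubbles are reported inside their enclosing superbubble, never as chain
members. An endpoint node incident to three or more bubbles breaks the chain
(chains are linear by definition; in practice a well-formed detection cannot
attach more than one bubble per node side, so this rule is defensive). Chains
are oriented from their lexicographically smaller outer endpoint and numbered
consecutively after sorting by that endpoint, making reports byte-stable.

Chain length is reported in two units, because "chain size" is ambiguous:
`length_in_bubbles`, and `length_in_bases` — the sum over member bubbles of
the longest source-to-sink walk in bases (dynamic programming over the
bubble's acyclic oriented subgraph, overlaps subtracted), with shared
endpoint nodes counted once. The base-pair convention is a definition made
here, chosen so that a chain over a haplotype with isolated SNPs recovers
exactly the haplotype length; any walk-based convention (longest, shortest,
reference-biased) would be defensible, and the longest walk was picked as the
most conservative span estimate.

## The synthetic fixture generator

`make_diploid_graph()` emulates the construction the package is designed to
analyze: a diploid sample's two haplotypes, k-merized into a de Bruijn graph
with `k - 1` overlaps, then compacted.

* The reference haplotype is generated with **all k-mers unique** (a
  restarted random walk that never re-uses a k-mer). Collapsed repeats are
  the main source of false-positive bubbles on real data; excluding them from
  fixtures makes the planted truth exact, and is precisely why passing these
  tests says nothing about repeat-induced artifacts on real graphs.
* Heterozygous SNPs are planted at positions at least `min_spacing` apart,
  with `min_spacing > k` required: two variants at distance `k` or less share
  no homozygous anchor k-mer between them, so their branches fuse into one
  locus. (Spacing of exactly `k` is *not* sufficient, which is easy to miss:
  an anchor k-mer needs a start position strictly between the two variant
  windows, and there are `d - k` such positions for variants at distance
  `d`.) The default spacing of `3k` stays well clear of the boundary. Each
  isolated SNP then yields exactly one simple bubble whose two branch unitigs
  are `2k - 1` bases long (`k` k-mers each), and all bubbles of a haplotype
  pair line up in one chain.
* **Clusters** of two SNPs at distance `< k` model the multi-sequence
  superbubble case. With only two haplotypes such a cluster still compacts to
  a single two-branch (hence simple) bubble, so each cluster is additionally
  covered by a third, recombinant sequence copy carrying the first cluster
  SNP only — the same multi-sample construction that produces superbubbles in
  de Bruijn graphs built from several individuals. The resulting locus is
  provably one non-simple superbubble (three partial paths with an internal
  join), and the generator verifies the aligned-columns property (every k-mer
  occurs at a single sequence position) before returning, retrying with fresh
  randomness otherwise.

`make_random_graph()` draws side-to-side edges independently over all end
pairs with short random sequences and overlaps in `0:2` — dense in exactly
the pathological configurations (orientation flips, tips, cycles, insertion
motifs) that stress the detector, and small enough for the oracle.

Both generators are deterministic given `seed` and restore the caller's RNG
state.

## Numerical and scale choices

The package is pure structure — no floating point anywhere; all comparisons
are exact set and integer equalities. Determinism is engineered throughout:
sorted node ids, sorted adjacency, canonical edge order, fixed JSON key
order, no timestamps inside reports.

Verification sizes were chosen to exercise the combinatorics, not to
benchmark: 500 random graphs of 4–12 nodes against the quadratic oracle
(the oracle, not the detector, is the binding constraint), the planted-SNP
grid over `n_snps ∈ {0, 1, 5, 20}` × `k ∈ {9, 21, 41}` on haplotypes of up to
~2.6 kb, and 100-replicate compaction and round-trip checks. The detector
itself has handled every graph thrown at it in linear-ish time; graphs with
millions of nodes are beyond what the pure-R reference implementation is
tuned for, though nothing in the algorithm changes with scale.

## Known limitations

* GFA1 S/L records only: no GFA2, rGFA, paths (P/W) or containments (C).
* Cyclic variation structures (vg-style snarls generalize superbubbles to
  these) are out of scope; directed cycles simply abort the local search.
* Fixtures model substitutions only — no indels, no sequencing errors, no
  coverage model — and deliberately exclude repeats (see above).
* Simple/insertion classification is only meaningful after compaction.
* Haplotype phasing across chains and VCF emission are downstream concerns
  of other tools, not of this package.
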
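---
title: "Genome ARGs: model, resolution semantics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome ARGs: model, resolution semantics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(argkit)
```

## The data model

`argkit` represents an ancestral recombination graph in genome-centric form:
a directed acyclic graph whose nodes are haploid genomes and whose edges
`(c, p, I)` say that child genome `c` inherited from parent genome `p` over
the interval set `I`. All coordinates are 0-based, continuous, and half-open
(`[left, right)`), on a shared coordinate space `[0, L)`; `L` is stored
explicitly rather than inferred from the largest endpoint, so that trailing
uninherited sequence is representable. Interval sets are kept in a canonical
form — sorted, disjoint, with abutting intervals merged — so that two sets
covering the same loci are `identical()`, and equality testing throughout
the package (forest merging, idempotence checks, byte-stable output) is
exact rather than tolerance-based.

Node times are optional and measured pastwards (parents older than
children). When every node is dated, validation additionally checks time
ordering along edges; with partial dating only the topological order is
required. A single edge may carry a multi-interval set, which is how
multiple crossovers per meiosis and gene conversion are expressed without
any dedicated event type.

Two deliberately redundant tree extractors are provided. `tree_at()` answers
"what is the genealogy at position x" by climbing pastwards from the samples
through the edges covering `x`; `trees()` recovers the whole sequence of
local trees with a left-to-right sweep over sorted edge endpoints, applying
removals before insertions at tied positions (so the
one-parent-per-locus invariant holds mid-sweep) and merging adjacent
identical forests into maximal intervals. The two implementations share no
code beyond the data model, and the test suite drives them against each
other on hundreds of simulated graphs. Regions where the sample lineages
have not fully coalesced yield forests with several roots rather than an
error: partially-coalesced and other approximate structures are first-class
citizens here, because inference tools emit them.

## Ancestral material and resolution

The *ancestral material* of a node is the set of loci at which it lies on an
inheritance path from at least one sample; `ancestral_material()` computes
exactly that, by propagating each sample's full genome pastwards and
intersecting with edge intervals.

Resolution (`simplify_garg()`) uses a slightly stronger notion, the one a
backwards-in-time coalescent simulation tracks: a segment stops being
informative once the *entire* sample set has coalesced at that locus. An
edge's resolved intervals are therefore

```
I  ∩  ( path-ancestral(child)  \  ancestor-of-all-samples(child) )
```

so material above a locus MRCA is truncated. This is what removes a "grand
MRCA" that sits above the points where every part of the genome has already
coalesced: all of its edges resolve to the empty set. The package keeps the
two notions separate on purpose — `ancestral_material()` answers a purely
topological question and is monotone in the sample set, while resolution
answers "what does this graph say about the ancestry of these samples".

## The four precision levels

Published ARGs come at different levels of precision, and the simplifier
mirrors that as four cumulative levels:

1. **resolve-only** — intersect, drop empty edges, drop non-sample nodes
   left without edges. Topology otherwise untouched; unary nodes survive.
2. **prune-singly-connected** — collapse reconvergent pass-through
   structures ("diamonds"): where two or more parallel chains of
   pure-unary nodes lead from one child to one ancestor without carrying
   any coalescence, the chains are replaced by a single direct edge
   carrying their union. These structures are unknowable in principle: no
   data could distinguish which parallel path a segment took. We define the
   level operationally by that reconvergence pattern, not as "every node
   whose removal leaves local trees unchanged" — the latter would also
   sweep up simple unary chain nodes and make the next level vacuous.
3. **prune-unary-everywhere** — remove nodes whose coalescent span is
   empty, reconnecting children to the next surviving ancestor locus by
   locus (children of a removed node compose their intervals with the
   removed node's parent edges; removed nodes are processed youngest first
   so chains compose). Times of removed nodes are discarded.
4. **full** — rewrite edges so that every surviving node–interval pair has
   at least two children in its local tree, the "fully simplified" form
   that default coalescent simulators emit. This level is implemented by
   re-emitting edges from the coalescent-only local tree sequence, which
   makes its defining property true by construction.

The restricted local trees over the samples are identical at every level
(verified against the sweep on simulated inputs), and every level is
idempotent. Node counts are non-increasing from level 1 to 4; edge counts
are non-increasing through level 3, but the final per-locus bypass can
*increase* the number of `(child, parent)` pairs, since a child that was
attached to one locally-unary parent everywhere may end up attached to
different ancestors in different regions. That is a real property of the
fully simplified encoding, not an implementation artefact, and is why the
locally-unary form is the more compact one for storage.

Nodes listed in `retain_nodes` (for example nodes marking recombination
events, which are unary by nature) are exempt from every pruning rule and
survive even if resolution leaves them without ancestral material.
`densify_ids = TRUE` renumbers survivors `0..n-1` in time order (topological
order with samples first when times are missing) for reproducible compact
tables; by default original ids are preserved, which is what the simulator's
periodic simplification relies on.

Per-node *coalescence spans* (`coalescence_spans()`) report, for each node,
its ancestral intervals, the sub-intervals where at least two child
lineages carrying ancestral material meet in it, and the ratio of the two
spans. A fraction strictly between 0 and 1 identifies a locally-unary node:
pass-through in some trees, a genuine coalescence elsewhere.

## Event ARGs and conversion

The classical encoding is also implemented: events (sample,
common-ancestor, recombination) with explicit `left`/`right` parent
designation on recombination nodes. We require the designation as input
rather than inferring it from ordering rules, because such rules differ
between authors and are a known source of ambiguity. Breakpoint routing is
half-open-consistent: a position exactly at breakpoint `b` follows the
right parent, matching the `[0, b)` / `[b, L)` annotation used in
conversion. `earg_tree_at()` traces local trees directly on the event graph
and serves as an independent oracle for the conversion path
(`earg_to_garg()` + resolution), which the tests exercise on randomly
generated event graphs. Only this abstract table format is read; native
formats of specific inference tools are out of scope.

## The Wright–Fisher recorder

`simulate_wf()` is the package's synthetic-data generator and a model of
prospective ARG recording: a closed diploid Wright–Fisher population of
`n_diploids` individuals per generation, run for `n_generations`, recording
every inheritance relationship. Per genome, a parent individual is drawn
uniformly (independent draws per genome; selfing allowed — the simplest
Wright–Fisher convention), the number of crossovers is Poisson with mean
`recomb_rate` (default 1 per genome per meiosis), crossover positions are
uniform on `(0, L)`, and segments alternate between the parent's two
genomes from a fair-coin starting phase. The random stream is consumed in a
fixed documented order (per generation: parents, crossover counts,
positions, phases), so a seed reproduces the node and edge tables exactly.
Founders carry no edges; lineages that fail to coalesce simply end there,
which the multi-root forests represent without special cases.

What this generator emulates: neutral genealogies with recombination in a
closed, panmictic, constant-size population, with full pedigree embedding.
What it does not: mutation and observed sequences, selection, migration and
population structure, varying population size, sex-specific recombination,
gene conversion (the data model supports it; the generator emits single
crossovers only), and crucially the noise and bias of *inferred* ARGs.
Passing tests on these simulations therefore validate the graph algorithms
exactly, but say nothing about robustness to inference error in real data.

Periodic simplification (`simplify_interval = k`) fully simplifies with
respect to the current generation every `k` generations, keeping original
ids. This is safe because any future sample's lineage passes through the
current generation, so every coalescence relevant to future samples is
either between current lineages (and preserved) or below them;
`periodic_simplify_equivalence()` checks the resulting invariance
empirically, and the test suite runs it across 50 random parameter draws.

As a calibration check that crosses the gARG machinery with classical
theory, the suite compares the mean pairwise coalescence time at a random
locus, over 200 replicates at 5 and 20 diploids (run for `4N` generations),
against an independent two-lineage tracing oracle that knows nothing about
graphs — two lineages each pick one of the `2N` genomes per generation and
coalesce on a collision, truncated at the simulated horizon exactly as the
graph measurement is. Agreement is required within three standard errors.

## Numerical choices and degenerate inputs

* Positions are doubles; no epsilon comparisons are used anywhere. Interval
  canonicalization makes equality exact, and serialization
  (`write_garg()`/`read_garg()`) prints integer-valued positions without a
  decimal point and everything else with 17 significant digits, so round
  trips are bit-exact and repeated writes byte-identical.
* Ties in the sweep: removals strictly before insertions.
* Coincident crossover positions in one meiosis cancel pairwise (the
  zero-length segment is dropped and the flanking segments merge), the
  measure-zero limit of the alternation model.
* Breakpoints at 0 or `L` in an event graph produce no edge for the empty
  side rather than an error.
* Validation never throws: `validate_garg()`/`validate_earg()` return
  violations as data, naming the rule and the offending ids; readers and
  the CLI turn them into errors with file/line context.
* Empty sample sets are rejected; unknown ids are reported by id.

## Problem sizes

The randomized suites run at sizes chosen to exercise every code path while
keeping the whole test run comfortably interactive: 200 simulated graphs
(2–5 diploids, 3–7 generations, recombination rate up to 2) for the
sweep-vs-oracle equivalence, 60 random event graphs for the conversion
oracle, 50 parameter draws for periodic-simplification equivalence, and
2 × 200 replicates for the coalescence-time calibration. The algorithms are
quadratic-ish in places (the sweep rebuilds each forest from the active
edge set); correctness, not asymptotic performance, is the contract here.

## Known limitations

* No mutations, sites, or sequence data; inheritance topology only.
* No import of native formats of existing inference tools.
* The diamond definition at level 2 is an operational interpretation of a
  structure that the literature defines by example; other reasonable
  definitions (e.g. treating any pass-through chain as removable) would
  blur the line between levels 2 and 3.
* The simplifier favours clarity over the asymptotically optimal
  algorithms used by production tree-sequence libraries; very large
  simulations will be slow.
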
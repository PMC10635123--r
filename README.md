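# argkit

Genome ancestral recombination graphs (gARGs) in R: local trees,
sample resolution ("simplify") and forward-time Wright–Fisher recording.

## The problem

Because of recombination, adjacent positions of a genome can have different
paths of genetic inheritance, so the genealogical tree relating a sample of
DNA sequences changes along the genome. The structure holding all of these
interwoven inheritance paths is an ancestral recombination graph (ARG).
Classical formalisms encode an ARG as a graph of *events* (common-ancestor
and breakpoint-annotated recombination events, an "eARG"); modern simulators
and large-scale inference tools instead work with structures in which nodes
are *genomes* and edges carry explicit inheritance intervals. `argkit`
implements that genome-centric formalism as a small, self-contained toolkit
for population geneticists who want to build, inspect, convert, simplify and
simulate such graphs from R.

## The model

A gARG is a directed acyclic graph `(N, S, E)` over a genome `[0, L)`:

* `N` — nodes, each a haploid genome, optionally dated (time measured
  pastwards) and labelled;
* `S ⊆ N` — the sampled genomes;
* `E` — edges `(c, p, I)`: child genome `c` inherits from parent genome `p`
  exactly over `I`, an ordered set of disjoint half-open intervals
  `[left, right)`.

Everything else is derived from this triple:

* the **local tree** at position `x` connects each node to its unique parent
  whose intervals cover `x` (`tree_at()`, and the sequential sweep
  `trees()` that recovers all local trees in one left-to-right pass);
* the **ancestral material** of a node is the set of loci at which it lies on
  an inheritance path from at least one sample (`ancestral_material()`);
* **simplification** (`simplify_garg()`) intersects every edge with the
  child's ancestral material (dropping material above the locus MRCA of the
  whole sample) and optionally prunes reconvergent "diamonds", nodes that
  are unary everywhere, and finally every locally-unary node–interval pair —
  the four precision levels in which published ARGs come;
* a classical **eARG** converts to a gARG by annotating the outbound edge of
  each common-ancestor event with `[0, L)` and the two outbound edges of a
  recombination event with breakpoint `b` with `[0, b)` and `[b, L)`
  (`earg_to_garg()`, `convert_and_resolve()`);
* a prospective diploid **Wright–Fisher** simulator records a gARG
  generation by generation, embedded in the pedigree it samples
  (`simulate_wf()`), with optional periodic simplification.

## Worked example

The package ships transcriptions of small worked examples
(`arg_fixtures()`). `fig1` is a gARG of 16 genomes (`a`–`p`) embedded in a
pedigree of eight diploid individuals: genome `a` inherited `[0,2)` from `e`
and `[2,10)` from `f`; genome `c` is the complementary recombinant.

```r
library(argkit)
fx <- arg_fixtures()
g  <- fx$fig1
g
#> gARG: 16 nodes (4 samples), 14 edge intervals, L = 10

trees(g)
#> local tree sequence: 3 forest(s) over [0, 10)
#>   [0, 2): 11 nodes, root(s) 14
#>   [2, 7): 10 nodes, root(s) 14
#>   [7, 10): 11 nodes, root(s) 14
```

The two recombination breakpoints (2 and 7) delineate three local trees, all
rooted in node 14 (`n`), the samples' most recent common ancestor. In the
middle region, samples `a` and `c` coalesce early, in node `f`:

```r
pairwise_mrca(trees(g), node_id(g, "a"), node_id(g, "c"))
#>   left right mrca
#> 1    0     2   14
#> 2    2     7    6      # node f
#> 3    7    10   14
```

`f` is ancestral over the whole genome but *coalescent* only on `[2,7)` —
a "locally unary" node with coalescence fraction 0.5:

```r
as.data.frame(coalescence_spans(g))[node_id(g, "f"), ]
#>   id ancestral_span coalescent_span fraction
#> 6  6             10               5      0.5
```

Converting the classical 17-event eARG example (`fig3`, samples `a`, `b`,
`c`) to a sample-resolved gARG removes the grand MRCA `q` — every part of
the genome has already coalesced in `k` or `p` — and drops the edge of the
recombination event at position 5, which fell entirely in non-ancestral
material:

```r
res <- convert_and_resolve(fx$fig3)
res$report
#> simplify report (level resolve-only): 2 of 17 nodes removed, 5 edges removed
```

Simulating and fully simplifying a small Wright–Fisher population:

```r
sim <- simulate_wf(n_diploids = 10, n_generations = 20, L = 100,
                   recomb_rate = 1, seed = 42)
sim$garg
#> gARG: 420 nodes (20 samples), 808 edge intervals, L = 100
simplify_garg(sim$garg, level = "full")$garg
#> gARG: 72 nodes (20 samples), 307 edge intervals, L = 100
```

The exhaustive recording shrinks six-fold once everything irrelevant to the
final generation's genetic ancestry is removed; at the intermediate
`"resolve-only"` level, 48 of 239 surviving nodes are locally unary
(coalescence fraction strictly between 0 and 1), the hallmark of
partially-precise ARG structures.

Local trees export as Newick (`export_newick()`), one line per genomic
interval, parseable by any standard tree reader.

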
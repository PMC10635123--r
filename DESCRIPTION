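Package: argkit
Title: Genome Ancestral Recombination Graphs: Local Trees, Simplification
    and Forward Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for representing and manipulating ancestral recombination
    graphs (ARGs) in the genome-ARG (gARG) form: a directed acyclic graph whose
    nodes are haploid genomes and whose edges are annotated with the disjoint
    genomic intervals over which a child genome inherits from a parent.
    Provides interval-set algebra, structural validation, recovery of the
    sequence of local genealogical trees along the genome, propagation and
    resolution of ancestral material for a sample set ("simplify") at four
    precision levels with per-node coalescence-span annotation, conversion of
    classical event-ARGs (common-ancestor and breakpoint-annotated
    recombination events) to sample-resolved gARGs, a prospective diploid
    Wright-Fisher recorder that generates gARGs embedded in a pedigree, plain
    TSV readers and writers for node and edge tables, Newick export of local
    trees, and worked-example fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    ape,
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
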
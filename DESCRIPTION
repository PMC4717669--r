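Package: genrearr
Title: Weighted Genome Rearrangement Distances and Ancestral Chromosome
    Structure Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing gene orders of chromosome structures that
    may mix linear and circular chromosomes, differ in gene content and
    carry paralogs.  Implements a near-linear common-graph algorithm for
    the minimum-weight sequence of double-, sesqui- and cut-and-join
    operations together with region deletions and insertions; breakpoint
    distance; paralog assignment by integer linear programming; and
    ancestral reconstruction on phylogenetic trees by minimum-spanning-tree
    and triple-contraction Steiner approximations with greedy descent
    refinement.  Includes brute-force oracles and a seeded evolution
    simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
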
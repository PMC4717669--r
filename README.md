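# genrearr

Weighted genome-rearrangement distances and ancestral chromosome-structure
reconstruction for gene-order data.

A *chromosome structure* is a set of linear and circular chromosomes whose
elements are signed genes, possibly with paralogs (`cox1`, `-ls3`,
`rpoC2.2`). Two structures may differ in gene content. Six weighted
operations transform one structure into another: double-cut-and-paste,
sesqui-cut-and-paste, cut, join, deletion of a maximal region of
source-private genes, and insertion of a region of target-private genes.
The *biological distance* between two structures is the minimum total weight
of such a sequence; the *breakpoint distance* counts extremity pairs glued
in one structure but not the other plus genes private to one structure.

The package implements:

* a near-linear **common-graph algorithm** for the minimum-weight operation
  sequence (`transform_to_final()`, `biological_distance()`). The common
  graph a+b has a node per extremity of a shared gene plus a node per
  maximal private-gene region; the algorithm closes conventional-edge
  regions into final 2-circles, combines path types to save operations, and
  pairs components so deletions of target-private regions (the most
  expensive operation, weight c) are replaced by cheaper joins. It is exact
  for equal gene content under the circular or linear weight pattern
  (over minimum-length sequences) and within the single weight d of the
  optimum when the five standard weights equal d and d &le; c &le; 2d;
* **paralog assignment by integer linear programming**
  (`build_matching_ilp()`, `solve_paralog_matching()`,
  `distance_with_paths()`, `breakpoint_matching()`): matching variables
  z[k,i,j] with block-border (x), alternation (y) and circle-indicator
  (u, p) variables whose optimum realizes the circular-case distance
  B + S1 - S2; paths are handled by closing them into circles at a cost of
  at most 2(n1+n2);
* **ancestral reconstruction** on or without a given tree
  (`distance_matrix()`, `build_tree_upgma()`, `steiner_first()`,
  `zelikovsky_second()`, `median_three()`, `descent_refine()`,
  `root_by_oneway()`): reduction to the minimum Steiner tree over the space
  of structures, an MST-based 2-approximation, the greedy triple-contraction
  11/6-approximation, and greedy descent that replaces internal-node
  structures by one-operation neighbours while the total edge distance G
  decreases;
* **brute-force oracles and a seeded simulator**
  (`bfs_shortest_sequence()`, `brute_force_steiner()`, `all_structures()`,
  `simulate_evolution()`) that make every algorithmic claim testable.

## Worked example

The two *Theileria* mitochondrial gene orders (printed in the package's
`inst/extdata/aconoidasida_mito.tsv`) differ by the presence of `ls2`:

```r
library(genrearr)
tab <- read.delim(system.file("extdata", "aconoidasida_mito.tsv",
                              package = "genrearr"))
tp <- parse_structure(paste0(tab$gene_order[tab$species == "Theileria_parva"],
                             " (L)"), "table1", name = "T_parva")
ta <- parse_structure(paste0(tab$gene_order[tab$species == "Theileria_annulata"],
                             " (L)"), "table1", name = "T_annulata")

breakpoint_distance(tp, ta)
#> [1] 4
biological_distance(tp, ta, weight_scheme("linear"))
#> biological distance: 1.15 (a->b 1.5, b->a 0.8) [HEURISTIC]
transform_to_final(tp, ta, weight_scheme("linear"))
#> rearrangement scenario T_parva -> T_annulata: 1 operation(s), total weight 1.5
#>   INSERT_REGION  w=1.5 + ls2
```

The breakpoint distance is 4: the two adjacencies flanking the `ls2` locus
are unshared on both sides (2 + 1 per direction around the insertion site)
plus the private gene counted once per structure it is missing from.
Transforming *T. parva* into *T. annulata* takes one insertion of the `ls2`
region at weight 1.5 (the linear-pattern insertion weight); the reverse
direction is one deletion at weight 0.8; the symmetric biological distance
is their mean, 1.15.

A command-line interface with `distance`, `matrix`, `tree`, `reconstruct`,
`ilp-size`, `simulate` and `validate-weights` subcommands is installed under
`inst/cli/genrearr`.

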
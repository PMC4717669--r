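---
title: "Weighted rearrangement distances and ancestral chromosome structures: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted rearrangement distances and ancestral chromosome structures: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genrearr)
```

## The model

A chromosome structure is a finite set of paths and circles whose directed
edges are genes: any number of linear and circular chromosomes, arbitrary
gene content, and paralogs written `family.j`. Gene lengths, intergenic
content and nucleotide sequence are outside the model. When two structures
`a` and `b` are compared, a gene present in both is *common* and a gene
present in one only is *special*.

Six operations transform `a` into `b`, each with a positive weight:

* **double-cut-and-paste** — cut two adjacencies and rejoin the four
  extremities in a new pairing;
* **sesqui-cut-and-paste** — cut one adjacency and join one freed extremity
  to a free extremity;
* **cut** and **join** — the two directions of cut-and-join;
* **deletion** of a maximal region of special `a`-genes (flanking
  extremities rejoin when the region was strictly internal);
* **insertion** of a region of special `b`-genes.

"Unnatural" variants are excluded: no cut strictly inside a special
`a`-region, no insertion into a special `a`-region, and no standard
operation that excises a special `a`-region into a new circle. The
biological distance is the minimum total weight of a transforming sequence;
the symmetric distance used for trees is the mean of the two directions.

### Weight patterns

Two named schemes order the weights by a non-strict descent; the third
("none") leaves them free. The descent values 1.5, 1.2, 1.1, 1, 0.9, 0.8
are assigned along the pattern order. The edge-operation tier names one
cut-and-join direction per pattern but must cover both; the package gives
that tier the two adjacent values:

| pattern  | insertion (c) | sesqui | join | cut | double | deletion |
|----------|---------------|--------|------|-----|--------|----------|
| circular | 1.5           | 1.2    | 1.1  | 1.0 | 0.9    | 0.8      |

| pattern | insertion (c) | double | sesqui | cut | join | deletion |
|---------|---------------|--------|--------|-----|------|----------|
| linear  | 1.5           | 1.2    | 1.1    | 1.0 | 0.9   | 0.8      |

The algorithm is exact in two regimes: (1) equal gene content under a
satisfied circular/linear pattern, where it attains the minimum weight among
minimum-length sequences; and (2) five standard weights equal to some `d`
with the insertion weight `c` in `[d, 2d]`, where the result is within an
additive `d` of the optimum. For arbitrary weights in `[0.8, 1.5]` it is a
heuristic; the test suite checks a 1.5x bound against a search oracle.

## The common graph and the five steps

The common graph `a+b` has one node per extremity of each common gene and
one node per maximal region of special genes, with edges labelled by the
source structure; a circular all-special chromosome contributes an isolated
special node carrying a loop. The target *final form* consists of isolated
conventional nodes and final 2-circles (a pair of extremities joined by one
`a`- and one `b`-edge). Operations on the `b` side of the graph mirror
inverse operations near the end of the output scenario; insertions never
appear on the graph itself, only in the replayed scenario.

1. **Step 1** deletes special `a`-loops (each is one region deletion).
2. **Step 2** consumes maximal regions of conventional edges: an internal
   edge is closed into a final 2-circle by a double (cutting the two
   opposite-side neighbours, merging special nodes that meet), an extreme
   edge by a sesqui, a singular edge by a join. Per region of length `l`
   this takes `floor(l/2)` operations, plus one for an odd region touching
   a path end, minus one for a region forming a whole circle — the quantity
   `S` below. When the double weighs no more than the sesqui the interior
   closures are preferred; otherwise closure proceeds from free path ends,
   which turns would-be doubles into sesquis at equal operation count.
3. **Step 3** combines the classified path types (odd `a`/`b`-paths 1a-3b',
   even types 1, 1', 1'', 2, 2', 3) according to the printed combination
   table; every action is a single sesqui or join that merges two special
   nodes and thereby saves one operation. Combinations whose outcome
   depends on which external edge is cut are kept *pending* (type 1_c) and
   materialized when step 4 decides the choice.
4. **Step 4** pairs the remaining components so that deletions of `b`-nodes
   — the most expensive operation — are replaced by joins of two `b`-nodes,
   then closes paths with non-hanging edges into circles and splices
   circles holding both node kinds into other components. Two action tables
   exist; the one used is selected by comparing the double and sesqui
   weights, and the degenerate-variant table matches the primed types
   exactly while the other matches aggregated types (2a covers 2a', 3b
   covers 3b', 1_b covers 1'', 2 covers 2'). The package additionally pairs
   isolated special `b`-nodes with each other whenever a cut is no dearer
   than an insertion: inserting their regions as one chromosome and cutting
   it apart is strictly better than separate insertions, and exhaustive
   search on small instances shows the additive-`d` guarantee requires it.
5. **Step 5** deletes what remains: isolated special nodes and loops,
   special nodes of leftover paths, and circles reduced by merging
   same-side special nodes pairwise (splitting off 2-circles) until only
   deletions remain.

Every graph operation is mirrored as an adjacency-level delta on the
evolving structures, so the emitted scenario replays from `a` to `b`
bit-exactly; the engine asserts this on every run.

### The weight formula

The scenario's cost decomposes over readily computed properties of the
initial graph: `C = B + S + (D − P) + eps (B' + n)`, with `B` the number of
special nodes (each leaves the graph through exactly one count-decreasing
operation — a merge or a deletion), `S` the step-2 operation count above,
`D − P` the operations that decrease nothing (closures and splices; `P`
counts the step-3 savings), `eps` the insertion weight minus one, `B'` the
initial circles with `b`-nodes only, and `n <= 2` the `b`-deletions beyond
them. `compute_invariants()` computes `B`, `S`, `B'` from the initial graph,
decomposes a bookkeeping run per category, and the suite asserts the
identities — including `C` equal to the total weight whenever the five
standard weights are 1. A constant per-type table for `D` alone is not
stable at the printed taxonomy's granularity (a type-1b path costs one
extra operation more when it retains an internal conventional edge), which
is why the decomposition, not a lookup table, is what the package verifies.

## Paralog assignment by integer linear programming

For circular structures under equal standard weights the distance is
`B + S1 − S2`: blocks (special regions), half-lengths of the maximal
conventional-edge regions, and conventional-edge circles. The ILP introduces
matching variables `z[k,i,j]` (row/column sums at most one), block-border
variables `x` (forced up when a matched gene neighbours an unmatched one),
alternation variables `y` (coupled across *potential neighbours* — an
`a`-pair and a `b`-pair sharing a gene-extremity type), and the circle
device `u, p`: integer `u_s <= m_s` equalized along matched neighbours with
`p_s` indicating that `u_s` attains `m_s`. The objective
`0.5 sum x + sum y − sum p` (plus the optional similarity penalty
`sum z (1 − s)`) therefore has optimum `B + S1 − S2`.

Two choices deserve note:

* `m_s` may take any value from 1 to the number of adjacent pairs. The
  package assigns *pairwise distinct* values 1..N. With a uniform value,
  every `u` on a conventional-edge circle attains the common bound and all
  its `p`s count, overcounting `S2`; with distinct values the `u`s on a
  circle are equal, so exactly the pair with the smallest `m_s` can attain
  its own bound — one `p` per circle, as intended.
* the border device misses a block spanning a whole chromosome (it has no
  borders). Chromosomes with no shared family contribute a constant 1 each;
  a single shared-family chromosome per side keeps at least one match via a
  hard row; otherwise soft indicator variables price the missed block
  exactly. The 200-family, 5-paralog reference instance keeps exactly
  13000 variables this way.

The per-family counts on that instance are 5000 `z` variables with 2000
constraints, 1000 `x` per side, 2000 `y` and 4000 `u/p` variables. The
coupling constraints are generated for every potential-neighbour pair —
25 per family and extremity type (five `a`-pairs times five `b`-pairs) —
because off-diagonal matchings need them for correctness; the compact
counting that pairs each extremity with a single partner would give 4000
rather than 20000 alternation rows but leaves off-diagonal optima
unconstrained. `ilp_size()` reports what the construction actually builds.

Structures with paths are handled by closing every path into a circle and
adding the number of closed paths; the result is within `2 (n1 + n2)` of
the true distance. The breakpoint counterpart minimizes the breakpoint
distance over bijections with a direct 0/1 program (matching variables plus
adjacency-preservation indicators); its only contract is equality with the
exhaustive-bijection minimum, which the suite checks.

No linear-programming backend is available in this stack, so the package
ships a small exact branch-and-bound solver (`R/milp.R`): interval
propagation to a fixpoint, branching over binary variables cheapest-side
first, and auxiliary integers (zero objective, at most one
positive-coefficient integer per row, as in this model) resolved by bound
propagation. The first optimum found under the deterministic branching
order is returned, so results are reproducible.

## Reconstruction

The reconstruction problem — a binary tree over `m` given structures with
structures at internal nodes minimizing the summed edge distances — reduces
to the minimum Steiner tree in the complete graph of all structures; by the
triangle inequality shortest paths are direct edges, so only the `m x m`
distance matrix is needed. Trees from distances use average-linkage
agglomeration (`build_tree_upgma()`, with neighbour joining as an option —
the variant is not pinned by the underlying procedure, so plain UPGMA was
chosen and NJ exposed).

* `steiner_first()` takes a Prim MST of the matrix (zero distances are kept
  by an epsilon shift, since the graph backend drops zero-weight edges) and
  converts it to a rooted binary arrangement: leaf copies are added under
  internal terminals, degree-2 chains spliced, non-binary nodes expanded
  left-deep in label order. Ratio 2.
* `zelikovsky_second()` greedily contracts terminal triples: medians `v(z)`
  and `d(z)` for every triple, then repeatedly the triple maximizing
  `w = t(G') − t(G'[z]) − d(z)`, zeroing two of the three triple edges
  (which two is immaterial for the spanning weight; the lexicographically
  first two are used) and maintaining the MST incrementally by the
  replace-heaviest-on-cycle rule. Ratio 11/6 for the breakpoint metric.
  Ties among equal-`w` triples resolve to the first in lexicographic order.
* `median_three()` is exhaustive over the structure universe for the
  breakpoint metric (guarded to 3-gene universes) and heuristic for the
  biological metric: walk the scenario from `a` to `b`, score every
  intermediate against the third structure, repeat over the three pairings
  and keep the best candidate.
* `descent_refine()` repeatedly applies, at whichever internal node offers
  it, the single operation whose replacement structure decreases the total
  edge distance `G` the most, until no strict decrease exists. The
  neighbourhood is all standard operations plus deletions of runs absent
  from every neighbour and single-gene insertions of genes a neighbour
  carries. `G` is non-increasing and the loop terminates at a local
  minimum. The recommended initialization is the exhaustive breakpoint
  arrangement on small alphabets (used by the tests); the MST arrangement
  serves otherwise.
* `root_by_oneway()` scans every node as root and keeps the rooting with
  the smallest total one-way (parent-to-child) distance. Edge midpoints add
  nothing here because a midpoint would carry one endpoint's structure and
  tie with rooting at that endpoint.

## Synthetic data and oracles

`random_structure()` and `simulate_evolution()` draw seeded structures and
apply sampled operations along a tree, recording the true arrangement. The
defaults (five genes, two events per edge, standard operations only) keep
gene content constant, which matches the regime where the distance
algorithm is exact and makes recovery checks interpretable; deletion and
insertion rates can be switched on but then leaf content drifts and
distances enter the heuristic regime. The generator does not emulate rate
heterogeneity, hotspots, or sequence-level processes, so green tests say
nothing about those aspects of real data.

`bfs_shortest_sequence()` is the independent optimum: uniform-cost search
over canonical states with all legal moves (insertions enumerate signed
orderings of subsets of the missing genes — optimal sequences may insert
several target regions as one chromosome and split it) and an admissible
A* bound from wrong and missing adjacencies and pending indels; a second
iterative-deepening search cross-checks it. `brute_force_steiner()` runs
Dreyfus-Wagner over the enumerated universe with metric closure.

## Numerical choices and problem sizes

Weights are compared with a 1e-12 tolerance; ties in the step-2 ordering
fall to the double-first branch ("does not exceed"). Components and rule
matches are processed in lexicographic order of their smallest node id, so
scenarios are deterministic. Canonical text form is the lexicographically
least rotation/reflection per chromosome with chromosomes sorted.

The validation sweeps enumerate all structure pairs with at most four gene
occurrences once per gene-relabelling isomorphism class (689 classes; the
raw count is 1936, and distances are invariant under renaming), plus seeded
random pairs with five to six occurrences. Random-weight, paralog,
path-closing, Steiner-ratio and descent sweeps use 60, 60, 40, 20 and 8
seeded instances respectively; the acceptance script uses 50 instances for
the Steiner ratio and 300 for the heuristic-regime ratio. These sizes keep
the full suite within a practical runtime while leaving every claim
exercised end to end.

## Known limitations

* The common-graph engine targets exactness only in the two regimes above;
  for arbitrary weights it is a bounded heuristic.
* The paralog ILP is exact for circular structures under equal standard
  weights; mixed topologies go through the path-closing approximation.
* The exhaustive breakpoint median (and hence the 11/6 algorithm's inner
  step) is limited to small gene universes; the biological median is a
  scenario-walk heuristic by construction.
* Greedy descent converges to a local minimum of the arrangement weight.
  On small alphabets where the exhaustive optimum can be computed, roughly
  a third of random instances end one operation above it, at arrangements
  where no single-node replacement — by any structure at all, not just a
  one-operation neighbour — lowers G; escaping them would need coordinated
  changes at two nodes, which the procedure does not attempt.
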
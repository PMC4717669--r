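## ---------------------------------------------------------------------------
## Ancestral reconstruction: the problem is reduced to a minimum Steiner
## tree in the (implicit) complete graph of all chromosome structures; by
## the triangle inequality the shortest path between two structures is the
## direct edge, so the terminal graph is just the pairwise distance matrix.
## The first algorithm takes a minimum spanning tree (ratio 2); the second
## adds median structures of terminal triples greedily (ratio 11/6); greedy
## descent then improves an arrangement edge by edge.
## ---------------------------------------------------------------------------

metric_fun <- function(metric, w) {
  if (metric == "breakpoint") {
    function(a, b) {
      if (has_paralogs(a) || has_paralogs(b)) breakpoint_matching(a, b)$distance
      else breakpoint_distance(a, b)
    }
  } else {
    function(a, b) {
      if (has_paralogs(a) || has_paralogs(b)) distance_with_paths(a, b)$value
      else biological_distance(a, b, w)$symmetric
    }
  }
}

has_paralogs <- function(s) {
  ids <- structure_genes(s)
  anyDuplicated(gene_family(ids)) > 0
}

#' Pairwise distance matrix of chromosome structures
#'
#' @param structures list of `chrom_structure` objects (named, or names are
#'   taken from the structures).
#' @param metric `"breakpoint"` or `"biological"`.
#' @param w weight scheme for the biological metric.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(structures, metric = c("breakpoint", "biological"),
                            w = weight_scheme("none")) {
  metric <- match.arg(metric)
  stopifnot(length(structures) >= 2L)
  f <- metric_fun(metric, w)
  n <- length(structures)
  labs <- names(structures)
  if (is.null(labs))
    labs <- vapply(seq_len(n), function(i) {
      nm <- structures[[i]]$name
      if (nzchar(nm)) nm else paste0("s", i)
    }, "")
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    D[i, j] <- D[j, i] <- f(structures[[i]], structures[[j]])
  }
  tri <- triangle_violations(D)
  if (tri > 0)
    warning(sprintf("distance matrix violates the triangle inequality on %d triple(s)", tri))
  D
}

triangle_violations <- function(D) {
  n <- nrow(D); bad <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n))
    if (D[i, j] > D[i, k] + D[k, j] + 1e-9) bad <- bad + 1L
  bad
}

#' Distance-based tree of structures
#'
#' Average-linkage agglomeration (a UPGMA variant) by default; neighbour
#' joining as an alternative.
#'
#' @param dm distance matrix from [distance_matrix()].
#' @param method `"upgma"` or `"nj"`.
#' @return an `ape` `phylo` tree (rooted for UPGMA).
#' @export
build_tree_upgma <- function(dm, method = c("upgma", "nj")) {
  method <- match.arg(method)
  if (method == "nj") return(ape::nj(stats::as.dist(dm)))
  hc <- stats::hclust(stats::as.dist(dm), method = "average")
  ape::as.phylo(hc)
}

## --- arranged trees ---------------------------------------------------------

## An arrangement assigns a structure to every node of a rooted binary tree.
## Internally: nodes is a list of list(id, parent, children, structure,
## label); the weight is the sum of symmetric distances over edges.
arranged_tree <- function(nodes, root, metric, w) {
  at <- structure(list(nodes = nodes, root = root, metric = metric, w = w),
                  class = "arranged_tree")
  at$weight <- arrangement_weight(at)
  at
}

#' Total distance of an arrangement over all tree edges
#' @param at an `arranged_tree`.
#' @return numeric weight.
#' @export
arrangement_weight <- function(at) {
  f <- metric_fun(at$metric, at$w)
  tot <- 0
  for (nd in at$nodes) {
    if (is.na(nd$parent)) next
    tot <- tot + f(at$nodes[[nd$parent]]$structure, nd$structure)
  }
  tot
}

#' @export
print.arranged_tree <- function(x, ...) {
  nl <- sum(vapply(x$nodes, function(n) length(n$children) == 0L, TRUE))
  cat(sprintf("arranged tree: %d leaves, %d nodes, %s weight %.4g\n",
              nl, length(x$nodes), x$metric, x$weight))
  invisible(x)
}

#' Newick topology of an arranged tree
#' @param at an `arranged_tree`.
#' @return Newick string.
#' @export
arranged_newick <- function(at) {
  rec <- function(id) {
    nd <- at$nodes[[id]]
    if (!length(nd$children)) return(nd$label)
    paste0("(", paste(vapply(nd$children, rec, ""), collapse = ","), ")", nd$label)
  }
  paste0(rec(at$root), ";")
}

## build an arranged tree from an undirected terminal tree (edge list) by the
## backward construction: root at a degree-2 node (or subdivide an edge),
## add a leaf copy under every internal terminal, binarize deterministically
tree_from_mst <- function(edges, structures, labels, metric, w) {
  n <- length(structures)
  if (n == 1L) {
    nodes <- list(list(id = 1L, parent = NA_integer_, children = integer(0),
                       structure = structures[[1]], label = labels[1]))
    return(arranged_tree(nodes, 1L, metric, w))
  }
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  deg <- lengths(adj)
  root0 <- which(deg == 2L)
  nodes <- list()
  new_node <- function(structure, label, parent = NA_integer_) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(id = id, parent = parent, children = integer(0),
                         structure = structure, label = label)
    if (!is.na(parent))
      nodes[[parent]]$children <<- c(nodes[[parent]]$children, id)
    id
  }
  build <- function(v, from, parent) {
    ## children in the unrooted tree
    kids <- sort(setdiff(adj[[v]], from))
    inner <- length(kids) > 0L
    vid <- new_node(structures[[v]], if (inner) "" else labels[v], parent)
    if (inner) {
      ## terminal with descendants: add a leaf copy carrying its structure
      new_node(structures[[v]], labels[v], vid)
      for (k in kids) build(k, v, vid)
    }
    vid
  }
  if (length(root0)) {
    r <- root0[1]
    rid <- build(r, integer(0), NA_integer_)
  } else {
    ## subdivide the lexicographically first edge
    e <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE][1, ]
    rid <- new_node(structures[[e[1]]], "")
    ## root copies structure of one endpoint
    a_id <- build(e[1], e[2], rid)
    b_id <- build(e[2], e[1], rid)
  }
  at <- structure(list(nodes = nodes, root = rid, metric = metric, w = w),
                  class = "arranged_tree")
  at <- binarize(at)
  at$weight <- arrangement_weight(at)
  at
}

## left-deep binarization of nodes with more than two children
binarize <- function(at) {
  repeat {
    big <- NULL
    for (nd in at$nodes) if (length(nd$children) > 2L) { big <- nd; break }
    if (is.null(big)) break
    kids <- big$children
    id <- length(at$nodes) + 1L
    at$nodes[[id]] <- list(id = id, parent = big$id, children = kids[-1],
                           structure = big$structure, label = "")
    for (k in kids[-1]) at$nodes[[k]]$parent <- id
    at$nodes[[big$id]]$children <- c(kids[1], id)
  }
  at
}

#' First reconstruction algorithm: minimum spanning tree (ratio 2)
#'
#' @param structures list of `chrom_structure` (at least 2).
#' @param metric `"breakpoint"` or `"biological"`.
#' @param w weight scheme.
#' @param dm optional precomputed distance matrix.
#' @return an `arranged_tree`.
#' @export
steiner_first <- function(structures, metric = c("breakpoint", "biological"),
                          w = weight_scheme("none"), dm = NULL) {
  metric <- match.arg(metric)
  if (is.null(dm)) dm <- distance_matrix(structures, metric, w)
  labs <- rownames(dm)
  el <- mst_weight_edges(dm)$edges
  tree_from_mst(el, structures, labs, metric, w)
}

## --- medians ----------------------------------------------------------------

#' Median structure of three structures
#'
#' Breakpoint metric: exhaustive search over all structures on subsets of
#' the union gene set (guarded to small instances).  Biological metric: the
#' scenario-walk heuristic -- transform a into b, score every intermediate
#' structure against the third, over all three pairings, and keep the best.
#'
#' @param a,b,c `chrom_structure` objects.
#' @param metric `"breakpoint"` or `"biological"`.
#' @param w weight scheme.
#' @return list(structure, d_z) where d_z is the summed distance to a, b, c.
#' @export
median_three <- function(a, b, c, metric = c("breakpoint", "biological"),
                         w = weight_scheme("none")) {
  metric <- match.arg(metric)
  f <- metric_fun(metric, w)
  if (metric == "breakpoint") {
    genes <- sort(unique(c(structure_genes(a), structure_genes(b),
                           structure_genes(c))))
    if (length(genes) > 3L)
      stop("exhaustive breakpoint median limited to 3-gene universes")
    univ <- all_structures(genes, exact = FALSE)
    best <- NULL; bd <- Inf
    for (s in univ) {
      d <- f(s, a) + f(s, b) + f(s, c)
      if (d < bd - 1e-12) { bd <- d; best <- s }
    }
    return(list(structure = best, d_z = bd))
  }
  cand <- list(a, b, c)
  prs <- list(c(1, 2), c(1, 3), c(2, 3))
  for (pr in prs) {
    x <- list(a, b, c)[[pr[1]]]; y <- list(a, b, c)[[pr[2]]]
    sc <- tryCatch(transform_to_final(x, y, w), error = function(e) NULL)
    if (is.null(sc)) next
    for (o in sc$ops) cand[[length(cand) + 1L]] <- adjset_to_structure(o$after)
  }
  bd <- Inf; best <- NULL
  seen <- character(0)
  for (s in cand) {
    k <- structure_key(s)
    if (k %in% seen) next
    seen <- c(seen, k)
    d <- f(s, a) + f(s, b) + f(s, c)
    if (d < bd - 1e-12) { bd <- d; best <- s }
  }
  list(structure = best, d_z = bd)
}

## --- the second (triple contraction) algorithm ------------------------------

mst_weight_edges <- function(D) {
  ## igraph drops zero-weight entries of an adjacency matrix, so shift all
  ## off-diagonal labels by a tiny epsilon before extracting the MST
  eps <- 1e-9
  D2 <- D + eps
  diag(D2) <- 0
  g <- igraph::graph_from_adjacency_matrix(D2, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  mt <- igraph::mst(g, algorithm = "prim")
  el <- igraph::as_edgelist(mt, names = FALSE)
  wsum <- sum(vapply(seq_len(nrow(el)), function(k) D[el[k, 1], el[k, 2]], 0))
  list(edges = el, weight = wsum)
}

## minimum spanning tree bookkeeping with the incremental zero-edge update:
## when a label is zeroed, either the edge is already in the tree or it
## replaces the heaviest edge on the tree cycle it closes
mst_zero_edge <- function(tree_edges, D, i, j) {
  in_tree <- any((tree_edges[, 1] == i & tree_edges[, 2] == j) |
                   (tree_edges[, 1] == j & tree_edges[, 2] == i))
  if (in_tree) return(tree_edges)
  ## path from i to j in the tree
  n <- max(tree_edges)
  adj <- vector("list", n)
  for (k in seq_len(nrow(tree_edges))) {
    a <- tree_edges[k, 1]; b <- tree_edges[k, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  par <- rep(NA_integer_, n)
  stack <- i; par[i] <- i
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    for (u in adj[[v]]) if (is.na(par[u])) { par[u] <- v; stack <- c(stack, u) }
  }
  path <- j; v <- j
  while (v != i) { v <- par[v]; path <- c(path, v) }
  ## heaviest edge on the cycle
  hw <- -Inf; he <- NULL
  for (t in seq_len(length(path) - 1L)) {
    a <- path[t]; b <- path[t + 1L]
    if (D[a, b] > hw) { hw <- D[a, b]; he <- c(a, b) }
  }
  if (hw <= 0) return(tree_edges)   # nothing gained
  drop <- which((tree_edges[, 1] == he[1] & tree_edges[, 2] == he[2]) |
                  (tree_edges[, 1] == he[2] & tree_edges[, 2] == he[1]))[1]
  tree_edges[drop, ] <- c(i, j)
  tree_edges
}

tree_weight <- function(tree_edges, D) {
  sum(vapply(seq_len(nrow(tree_edges)), function(k)
    D[tree_edges[k, 1], tree_edges[k, 2]], 0))
}

#' Second reconstruction algorithm: greedy triple contraction (ratio 11/6)
#'
#' @inheritParams steiner_first
#' @return an `arranged_tree`.
#' @export
zelikovsky_second <- function(structures, metric = c("breakpoint", "biological"),
                              w = weight_scheme("none"), dm = NULL) {
  metric <- match.arg(metric)
  m <- length(structures)
  if (m < 3L) return(steiner_first(structures, metric, w, dm))
  if (is.null(dm)) dm <- distance_matrix(structures, metric, w)
  labs <- rownames(dm)
  f <- metric_fun(metric, w)
  ## medians of all triples
  trips <- utils::combn(m, 3L)
  med <- vector("list", ncol(trips))
  dz <- numeric(ncol(trips))
  for (t in seq_len(ncol(trips))) {
    z <- trips[, t]
    r <- median_three(structures[[z[1]]], structures[[z[2]]], structures[[z[3]]],
                      metric, w)
    med[[t]] <- r$structure
    dz[t] <- r$d_z
  }
  D <- dm
  ms <- mst_weight_edges(D)
  tree_edges <- ms$edges
  A <- integer(0)
  repeat {
    tG <- tree_weight(tree_edges, D)
    best_w <- 0; best_t <- 0L; best_state <- NULL
    for (t in seq_len(ncol(trips))) {
      z <- trips[, t]
      ## zero two of the three edges of the triple
      D2 <- D
      D2[z[1], z[2]] <- D2[z[2], z[1]] <- 0
      D2[z[2], z[3]] <- D2[z[3], z[2]] <- 0
      te <- mst_zero_edge(tree_edges, D2, z[1], z[2])
      te <- mst_zero_edge(te, D2, z[2], z[3])
      wv <- tG - tree_weight(te, D2) - dz[t]
      if (wv > best_w + 1e-12) { best_w <- wv; best_t <- t; best_state <- list(D2, te) }
    }
    if (best_t == 0L) break
    D <- best_state[[1]]
    tree_edges <- best_state[[2]]
    A <- c(A, best_t)
    if (length(A) >= m) break
  }
  ## step 4: MST over terminals plus the selected medians, true distances
  all_str <- c(structures, med[A])
  labs2 <- c(labs, if (length(A)) paste0("med", seq_along(A)) else character(0))
  n2 <- length(all_str)
  D2 <- matrix(0, n2, n2, dimnames = list(labs2, labs2))
  D2[seq_len(m), seq_len(m)] <- dm
  if (n2 > m) {
    for (i in seq_len(n2)) for (j in seq_len(n2)) {
      if (j <= i || (i <= m && j <= m)) next
      D2[i, j] <- D2[j, i] <- f(all_str[[i]], all_str[[j]])
    }
  }
  ms2 <- mst_weight_edges(D2)
  at <- tree_from_mst(ms2$edges, all_str, labs2, metric, w)
  prune_nonterminal_leaves(at, labs)
}

## remove non-terminal leaves and unlabelled degree-1/degree-2 chains that
## the Steiner-to-reconstruction transform leaves behind
prune_nonterminal_leaves <- function(at, terminal_labels) {
  repeat {
    drop <- NULL
    for (nd in at$nodes) {
      if (is.null(nd)) next
      if (!length(nd$children) && !(nd$label %in% terminal_labels)) { drop <- nd; break }
    }
    if (is.null(drop)) break
    p <- drop$parent
    at$nodes[[p]]$children <- setdiff(at$nodes[[p]]$children, drop$id)
    at$nodes[drop$id] <- list(NULL)
  }
  ## splice out degree-2 internal chains
  repeat {
    mid <- NULL
    for (nd in at$nodes) {
      if (is.null(nd)) next
      if (length(nd$children) == 1L && !is.na(nd$parent)) { mid <- nd; break }
    }
    if (is.null(mid)) break
    p <- mid$parent; ch <- mid$children[1]
    at$nodes[[p]]$children <- sort(c(setdiff(at$nodes[[p]]$children, mid$id), ch))
    at$nodes[[ch]]$parent <- p
    at$nodes[mid$id] <- list(NULL)
  }
  ## root with single child: promote
  while (!is.null(at$nodes[[at$root]]) && length(at$nodes[[at$root]]$children) == 1L) {
    ch <- at$nodes[[at$root]]$children[1]
    at$nodes[at$root] <- list(NULL)
    at$nodes[[ch]]$parent <- NA_integer_
    at$root <- ch
  }
  at$nodes <- lapply(at$nodes, function(x) x)
  at$weight <- arrangement_weight_safe(at)
  at
}

arrangement_weight_safe <- function(at) {
  f <- metric_fun(at$metric, at$w)
  tot <- 0
  for (nd in at$nodes) {
    if (is.null(nd) || is.na(nd$parent)) next
    tot <- tot + f(at$nodes[[nd$parent]]$structure, nd$structure)
  }
  tot
}

## --- greedy descent ---------------------------------------------------------

#' Greedy descent refinement of an arrangement
#'
#' Repeatedly applies, at whichever internal node offers it, the single
#' operation whose replacement structure gives the greatest strict decrease
#' of the total biological distance G over all edges; stops at a local
#' minimum.
#'
#' @param at an `arranged_tree` (biological metric recommended).
#' @param w weight scheme.
#' @param max_iter safety cap.
#' @return the refined `arranged_tree`.
#' @export
descent_refine <- function(at, w = at$w, max_iter = 100L) {
  at$w <- w
  dcache <- new.env(parent = emptyenv())
  dist2 <- function(x, y) {
    kx <- structure_key(x); ky <- structure_key(y)
    key <- if (kx < ky) paste(kx, ky) else paste(ky, kx)
    if (!is.null(v <- dcache[[key]])) return(v)
    v <- biological_distance(x, y, w)$symmetric
    dcache[[key]] <- v
    v
  }
  node_cost <- function(at, id, s) {
    nd <- at$nodes[[id]]
    tot <- 0
    if (!is.na(nd$parent)) tot <- tot + dist2(at$nodes[[nd$parent]]$structure, s)
    for (ch in nd$children) tot <- tot + dist2(s, at$nodes[[ch]]$structure)
    tot
  }
  internal <- function(at) {
    ids <- integer(0)
    for (nd in at$nodes) if (!is.null(nd) && length(nd$children)) ids <- c(ids, nd$id)
    ids
  }
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > max_iter) break
    best_gain <- 0; best <- NULL
    for (id in internal(at)) {
      cur <- at$nodes[[id]]$structure
      base <- node_cost(at, id, cur)
      nbr_genes <- unique(unlist(c(
        lapply(at$nodes[[id]]$children, function(ch) structure_genes(at$nodes[[ch]]$structure)),
        if (!is.na(at$nodes[[id]]$parent))
          list(structure_genes(at$nodes[[at$nodes[[id]]$parent]]$structure)))))
      for (s2 in neighbor_structures(cur, nbr_genes)) {
        gain <- base - node_cost(at, id, s2)
        if (gain > best_gain + 1e-9) { best_gain <- gain; best <- list(id = id, s = s2) }
      }
    }
    if (is.null(best)) break
    at$nodes[[best$id]]$structure <- best$s
  }
  at$weight <- arrangement_weight_safe(at)
  at
}

## all structures one operation away: standard operations plus deletions of
## runs absent from every neighbour and single-gene insertions of genes some
## neighbour carries
neighbor_structures <- function(s, neighbor_genes) {
  x <- as_adjset(s)
  out <- list()
  push <- function(y) {
    st <- tryCatch(adjset_to_structure(y), error = function(e) NULL)
    if (!is.null(st)) out[[length(out) + 1L]] <<- st
  }
  adj <- x$adj
  for (a1 in adj) push(op_cut(x, a1))
  frees <- free_extremities(x)
  if (length(frees) > 1L) {
    cmb <- utils::combn(frees, 2L)
    for (k in seq_len(ncol(cmb))) push(op_join(x, cmb[1, k], cmb[2, k]))
  }
  if (length(adj) > 1L) {
    cmb <- utils::combn(adj, 2L)
    for (k in seq_len(ncol(cmb))) for (pr in 1:2)
      push(op_dcj(x, cmb[1, k], cmb[2, k], pr))
  }
  for (a1 in adj) {
    p <- split_adj(a1)[[1]]
    for (keep in p) for (fe in frees) push(op_sesqui(x, a1, keep, fe))
  }
  dead <- setdiff(x$genes, neighbor_genes)
  if (length(dead)) for (run in special_runs(x, setdiff(x$genes, dead)))
    push(op_delete_region(x, run))
  for (gnew in setdiff(neighbor_genes, x$genes)) {
    for (sgn in c(1L, -1L)) {
      push(op_insert_region(x, gnew, sgn, NULL))
      for (a1 in adj) push(op_insert_region(x, gnew, sgn, a1))
    }
  }
  out
}

#' Build an arranged tree on a fixed topology
#'
#' @param tree an `ape` `phylo` (rooted) or Newick string.
#' @param leaves named list of `chrom_structure` matching the tip labels.
#' @param init optional list of structures for the internal nodes (indexed
#'   by ape node number); defaults to copying the first descendant leaf.
#' @param metric,w metric for the arrangement weight.
#' @return an `arranged_tree`.
#' @export
arranged_from_phylo <- function(tree, leaves, init = NULL,
                                metric = "biological", w = weight_scheme("none")) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  parent <- rep(NA_integer_, nnode)
  for (k in seq_len(nrow(tree$edge)))
    parent[tree$edge[k, 2]] <- tree$edge[k, 1]
  first_leaf <- function(v) {
    while (v > ntip) v <- tree$edge[tree$edge[, 1] == v, 2][1]
    v
  }
  nodes <- vector("list", nnode)
  for (v in seq_len(nnode)) {
    s <- if (v <= ntip) leaves[[tree$tip.label[v]]]
    else if (!is.null(init) && !is.null(init[[v]])) init[[v]]
    else leaves[[tree$tip.label[first_leaf(v)]]]
    nodes[[v]] <- list(id = v, parent = parent[v],
                       children = sort(tree$edge[tree$edge[, 1] == v, 2]),
                       structure = s,
                       label = if (v <= ntip) tree$tip.label[v] else "")
  }
  arranged_tree(nodes, ntip + 1L, metric, w)
}

#' Root an arrangement by total one-way distance
#'
#' Evaluates every node as root and keeps the rooting minimizing the sum of
#' one-way (parent to child) biological distances over all directed edges.
#'
#' @param at an `arranged_tree`.
#' @param w weight scheme.
#' @return the re-rooted `arranged_tree` (with `$oneway_total`).
#' @export
root_by_oneway <- function(at, w = at$w) {
  ids <- vapply(Filter(Negate(is.null), at$nodes), `[[`, 1L, "id")
  ## undirected adjacency
  adj <- list()
  for (nd in at$nodes) {
    if (is.null(nd) || is.na(nd$parent)) next
    adj[[as.character(nd$id)]] <- c(adj[[as.character(nd$id)]], nd$parent)
    adj[[as.character(nd$parent)]] <- c(adj[[as.character(nd$parent)]], nd$id)
  }
  oneway <- function(x, y) transform_to_final(x, y, w)$total_weight
  best <- NULL; bw <- Inf
  for (r in ids) {
    tot <- 0
    seen <- c(r); stack <- c(r)
    while (length(stack)) {
      v <- stack[1]; stack <- stack[-1]
      for (u in adj[[as.character(v)]]) {
        if (u %in% seen) next
        seen <- c(seen, u); stack <- c(stack, u)
        tot <- tot + oneway(at$nodes[[v]]$structure, at$nodes[[u]]$structure)
      }
    }
    if (tot < bw - 1e-12) { bw <- tot; best <- r }
  }
  ## reroot at best
  reparent <- function(at, r) {
    par <- rep(NA_integer_, length(at$nodes))
    seen <- c(r); stack <- c(r)
    while (length(stack)) {
      v <- stack[1]; stack <- stack[-1]
      for (u in adj[[as.character(v)]]) {
        if (u %in% seen) next
        par[u] <- v; seen <- c(seen, u); stack <- c(stack, u)
      }
    }
    for (i in seq_along(at$nodes)) {
      if (is.null(at$nodes[[i]]) || length(at$nodes[[i]]) == 0L) next
      at$nodes[[i]]$parent <- par[i]
      at$nodes[[i]]$children <- sort(which(par == i))
    }
    at$root <- r
    at
  }
  at <- reparent(at, best)
  at$oneway_total <- bw
  at$weight <- arrangement_weight_safe(at)
  at
}
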
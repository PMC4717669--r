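## ---------------------------------------------------------------------------
## Engine primitives: graph surgery on the common graph mirrored, operation
## by operation, onto the two evolving structures.  Operations on the a side
## transform a forwards; operations on the b side transform b backwards and
## are inverted when the scenario is assembled.  Every primitive logs an
## adjacency delta sufficient to replay the scenario on plain structures.
## ---------------------------------------------------------------------------

## ports: a special node stores its region as signed tokens; port "L" is the
## tail extremity of the first token, port "R" the head of the last.
port_ext <- function(g, S, port) {
  tok <- g$tokens[[S]]
  sgn <- ifelse(startsWith(tok, "-"), -1L, 1L)
  id <- sub("^-", "", tok)
  n <- length(id)
  if (port == "L") ext_tail(id[1], sgn[1]) else ext_head(id[n], sgn[n])
}

spec_ids <- function(g, S) sub("^-", "", g$tokens[[S]])

## which port of special node S a given edge uses
edge_port <- function(g, i, S) {
  if (g$e_n1[i] == S && g$e_n2[i] == S) stop("loop edge has both ports")
  if (g$e_n1[i] == S) g$e_p1[i] else g$e_p2[i]
}

free_port <- function(g, S) {
  used <- character(0)
  for (i in g$inc[[S]]) {
    if (g$e_n1[i] == S && g$e_n2[i] == S) used <- c(used, "L", "R")
    else used <- c(used, edge_port(g, i, S))
  }
  setdiff(c("L", "R"), used)
}

## endpoint descriptor: conventional extremity id, or special node + port
pt <- function(node, port = NA_character_) list(node = node, port = port)

pt_ext <- function(g, p) {
  if (g$kind[[p$node]] == "conv") p$node else port_ext(g, p$node, p$port)
}

## --- engine state ----------------------------------------------------------

eng_new <- function(a, b, w) {
  st <- new.env(parent = emptyenv())
  st$g <- build_common_graph(a, b)
  st$sa <- as_adjset(a); st$sb <- as_adjset(b)
  st$w <- w
  st$log <- list()
  st$pending <- list()
  st$phase <- "s0"
  st$last_nspec <- sum(st$g$kind == "spec")
  st
}

eng_log <- function(st, side, fwd_kind, removed, added,
                    genes_removed = character(0), tokens = NULL) {
  x <- if (side == "a") st$sa else st$sb
  ## apply delta to the evolving structure, with legality checks
  stopifnot(all(removed %in% x$adj))
  x$adj <- sort(c(setdiff(x$adj, removed), added))
  if (length(genes_removed)) x$genes <- setdiff(x$genes, genes_removed)
  if (side == "a") st$sa <- x else st$sb <- x
  ns <- sum(st$g$kind == "spec")
  delta <- st$last_nspec - ns
  st$last_nspec <- ns
  st$log[[length(st$log) + 1L]] <-
    list(side = side, fwd = fwd_kind, weight = op_weight(st$w, fwd_kind),
         removed = removed, added = added, genes = genes_removed,
         tokens = tokens, phase = st$phase, dspec = delta)
  invisible(st)
}

## forward kind of a graph operation on a given side
gk_fwd <- function(gkind, side) {
  if (side == "a") switch(gkind, cut = "cut", join = "join", dcj = "double",
                          sesqui = "sesqui", delnode = "del_a")
  else switch(gkind, cut = "join", join = "cut", dcj = "double",
              sesqui = "sesqui", delnode = "ins_b")
}

## --- graph edge helpers with ports ----------------------------------------

cg_add_edge_p <- function(g, p1, p2, side) {
  i <- cg_add_edge(g, p1$node, p2$node, side)
  g$e_p1[i] <- p1$port; g$e_p2[i] <- p2$port
  i
}

edge_pts <- function(g, i) {
  list(pt(g$e_n1[i], g$e_p1[i]), pt(g$e_n2[i], g$e_p2[i]))
}

edge_adj_key <- function(g, i) {
  ps <- edge_pts(g, i)
  adj_key(pt_ext(g, ps[[1]]), pt_ext(g, ps[[2]]))
}

## merge two same-side special nodes that have become adjacent through edge i
spec_merge <- function(g, i) {
  S1 <- g$e_n1[i]; S2 <- g$e_n2[i]
  p1 <- g$e_p1[i]; p2 <- g$e_p2[i]
  stopifnot(g$kind[[S1]] == "spec", g$kind[[S2]] == "spec",
            g$side[[S1]] == g$side[[S2]], S1 != S2)
  t1 <- g$tokens[[S1]]; t2 <- g$tokens[[S2]]
  flip1 <- p1 == "L"; flip2 <- p2 == "R"
  if (flip1) t1 <- rev_comp_tokens(t1)
  if (flip2) t2 <- rev_comp_tokens(t2)
  side <- g$side[[S1]]
  cg_del_edge(g, i)
  ## reattach surviving edges: S1's remaining edge lands on merged L,
  ## S2's on merged R; ports flip along with the token orientation
  M <- S1  # reuse id S1 for the merged node
  g$tokens[[M]] <- c(t1, t2)
  remap <- function(S, flipped, new_port) {
    for (j in g$inc[[S]]) {
      if (g$e_n1[j] == S) { g$e_p1[j] <- new_port; if (S != M) g$e_n1[j] <- M }
      if (g$e_n2[j] == S) { g$e_p2[j] <- new_port; if (S != M) g$e_n2[j] <- M }
      if (S != M) g$inc[[M]] <- c(g$inc[[M]], j)
    }
    if (S != M) g$inc[[S]] <- integer(0)
  }
  remap(S1, flip1, "L")
  remap(S2, flip2, "R")
  ## remove S2 bookkeeping
  g$kind <- g$kind[names(g$kind) != S2]
  g$inc[[S2]] <- NULL
  g$tokens[[S2]] <- NULL
  g$side <- g$side[names(g$side) != S2]
  g$loop <- g$loop[names(g$loop) != S2]
  M
}

## --- logged graph operations -----------------------------------------------

## cut edge i
eng_cut <- function(st, i, log = TRUE) {
  g <- st$g
  side <- g$e_side[i]
  key <- edge_adj_key(g, i)
  cg_del_edge(g, i)
  if (log) eng_log(st, side, gk_fwd("cut", side), removed = key, added = character(0))
  invisible(key)
}

## join endpoints p1, p2 (pt descriptors) on a side; merges special nodes
eng_join <- function(st, p1, p2, side, log = TRUE) {
  g <- st$g
  key <- adj_key(pt_ext(g, p1), pt_ext(g, p2))
  i <- cg_add_edge_p(g, p1, p2, side)
  if (g$kind[[p1$node]] == "spec" && g$kind[[p2$node]] == "spec" &&
      p1$node != p2$node)
    spec_merge(g, i)
  if (log) eng_log(st, side, gk_fwd("join", side), removed = character(0), added = key)
  invisible(i)
}

## double-cut-and-paste: cut edges i1, i2 (same side, non-incident), rejoin
## the four ends as (a1,b1) and (a2,b2) where a = ends of i1, b = ends of i2;
## `pairing` selects which end of i2 meets which end of i1
eng_dcj <- function(st, i1, i2, pair1, pair2) {
  g <- st$g
  side <- g$e_side[i1]
  stopifnot(g$e_side[i2] == side)
  k1 <- edge_adj_key(g, i1); k2 <- edge_adj_key(g, i2)
  cg_del_edge(g, i1); cg_del_edge(g, i2)
  a1 <- adj_key(pt_ext(g, pair1[[1]]), pt_ext(g, pair1[[2]]))
  j1 <- cg_add_edge_p(g, pair1[[1]], pair1[[2]], side)
  absorbed <- NA_character_
  if (g$kind[[pair1[[1]]$node]] == "spec" && g$kind[[pair1[[2]]$node]] == "spec" &&
      pair1[[1]]$node != pair1[[2]]$node) {
    spec_merge(g, j1)
    absorbed <- pair1[[2]]$node   # its surviving port maps to merged "R"
  }
  fix <- function(p) if (!is.na(absorbed) && p$node == absorbed)
    pt(pair1[[1]]$node, "R") else p
  pair2 <- lapply(pair2, fix)
  a2 <- adj_key(pt_ext(g, pair2[[1]]), pt_ext(g, pair2[[2]]))
  j2 <- cg_add_edge_p(g, pair2[[1]], pair2[[2]], side)
  if (g$kind[[pair2[[1]]$node]] == "spec" && g$kind[[pair2[[2]]$node]] == "spec" &&
      pair2[[1]]$node != pair2[[2]]$node) spec_merge(g, j2)
  eng_log(st, side, gk_fwd("dcj", side), removed = c(k1, k2), added = c(a1, a2))
  invisible(c(j1, j2))
}

## sesqui: cut edge i, join the end given by keep (pt) to target (pt)
eng_sesqui <- function(st, i, keep, target) {
  g <- st$g
  side <- g$e_side[i]
  kcut <- edge_adj_key(g, i)
  cg_del_edge(g, i)
  kadd <- adj_key(pt_ext(g, keep), pt_ext(g, target))
  j <- cg_add_edge_p(g, keep, target, side)
  if (g$kind[[keep$node]] == "spec" && g$kind[[target$node]] == "spec" &&
      keep$node != target$node) spec_merge(g, j)
  eng_log(st, side, gk_fwd("sesqui", side), removed = kcut, added = kadd)
  invisible(st)
}

## delete special node S (accessory operation: deletion on side a mirrors a
## region deletion, on side b a region insertion when the scenario is read
## forwards).  If S had two conventional neighbours they are joined.
eng_delnode <- function(st, S) {
  g <- st$g
  side <- g$side[[S]]
  ids <- spec_ids(g, S)
  tokens <- g$tokens[[S]]
  removed <- character(0); conv_nbr <- list()
  for (i in g$inc[[S]]) {
    if (g$e_n1[i] == S && g$e_n2[i] == S) {
      ## special loop: region is a circular chromosome
      removed <- c(removed, edge_adj_key(g, i))
    } else {
      o <- cg_other_end(g, i, S)
      removed <- c(removed, edge_adj_key(g, i))
      if (g$kind[[o]] == "conv") conv_nbr[[length(conv_nbr) + 1L]] <- pt(o)
    }
  }
  ## internal adjacencies of the region
  tok <- tokens
  sgn <- ifelse(startsWith(tok, "-"), -1L, 1L)
  id <- sub("^-", "", tok)
  n <- length(id)
  if (n > 1L) removed <- c(removed, adj_key(ext_head(id, sgn)[-n], ext_tail(id, sgn)[-1]))
  cg_del_node(st$g, S)
  added <- character(0)
  if (length(conv_nbr) == 2L) {
    added <- adj_key(conv_nbr[[1]]$node, conv_nbr[[2]]$node)
    cg_add_edge_p(st$g, conv_nbr[[1]], conv_nbr[[2]], side)
  }
  eng_log(st, side, gk_fwd("delnode", side), removed = unique(removed),
          added = added, genes_removed = ids, tokens = tokens)
  invisible(st)
}

## --- close a conventional edge into a final 2-circle ------------------------

## the twin edge on the opposite side is created by a double (both opposite
## neighbours present), a sesqui (one) or a cut-and-join (none)
close_edge <- function(st, i) {
  g <- st$g
  u <- g$e_n1[i]; v <- g$e_n2[i]
  s2 <- if (g$e_side[i] == "a") "b" else "a"
  eu <- cg_edges_of(g, u, s2); ev <- cg_edges_of(g, v, s2)
  stopifnot(length(eu) <= 1L, length(ev) <= 1L)
  if (length(eu) && length(ev)) {
    pu <- edge_pts(g, eu)
    ou <- if (pu[[1]]$node == u) pu[[2]] else pu[[1]]
    pv <- edge_pts(g, ev)
    ov <- if (pv[[1]]$node == v) pv[[2]] else pv[[1]]
    stopifnot(eu != ev)
    eng_dcj(st, eu, ev, list(pt(u), pt(v)), list(ou, ov))
  } else if (length(eu)) {
    eng_sesqui(st, eu, pt(u), pt(v))
  } else if (length(ev)) {
    eng_sesqui(st, ev, pt(v), pt(u))
  } else {
    eng_join(st, pt(u), pt(v), s2)
  }
  invisible(st)
}
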
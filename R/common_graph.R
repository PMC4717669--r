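## ---------------------------------------------------------------------------
## The common graph a+b of two structures.  Nodes are extremities of common
## genes ("conventional") plus maximal regions of source-private ("special")
## genes, one node per region.  Edges record adjacency in a or in b;
## a conventional edge joins two conventional nodes, a special edge joins a
## conventional node to a special node of the same source.  A circular
## all-special chromosome contributes an isolated special node with a loop.
## The graph is mutable (environment-based): the transformation engine
## rewrites it into the final form of isolated conventional nodes and final
## 2-circles.
## ---------------------------------------------------------------------------

cg_new <- function() {
  g <- new.env(parent = emptyenv())
  g$kind <- character(0)        # node id -> "conv" | "spec"
  g$side <- character(0)        # special node id -> "a" | "b"
  g$tokens <- list()            # special node id -> signed gene tokens
  g$loop <- logical(0)          # special node id -> has special loop
  g$e_n1 <- character(0); g$e_n2 <- character(0); g$e_side <- character(0)
  g$e_p1 <- character(0); g$e_p2 <- character(0)
  g$e_alive <- logical(0)
  g$inc <- list()               # node id -> integer edge indices
  g$nspec <- 0L
  g
}

cg_add_node <- function(g, id, kind, side = NA_character_, tokens = NULL,
                        loop = FALSE) {
  g$kind[id] <- kind
  if (kind == "spec") {
    g$side[id] <- side
    g$tokens[[id]] <- tokens
    g$loop[id] <- loop
  }
  g$inc[[id]] <- integer(0)
  id
}

cg_add_edge <- function(g, n1, n2, side, p1 = NA_character_, p2 = NA_character_) {
  i <- length(g$e_n1) + 1L
  g$e_n1[i] <- n1; g$e_n2[i] <- n2; g$e_side[i] <- side; g$e_alive[i] <- TRUE
  g$e_p1[i] <- p1; g$e_p2[i] <- p2
  g$inc[[n1]] <- c(g$inc[[n1]], i)
  if (n2 != n1) g$inc[[n2]] <- c(g$inc[[n2]], i)
  i
}

cg_del_edge <- function(g, i) {
  g$e_alive[i] <- FALSE
  g$inc[[g$e_n1[i]]] <- setdiff(g$inc[[g$e_n1[i]]], i)
  g$inc[[g$e_n2[i]]] <- setdiff(g$inc[[g$e_n2[i]]], i)
  invisible(g)
}

cg_del_node <- function(g, id) {
  for (i in g$inc[[id]]) cg_del_edge(g, i)
  g$kind <- g$kind[names(g$kind) != id]
  g$inc[[id]] <- NULL
  if (!is.null(g$tokens[[id]])) g$tokens[[id]] <- NULL
  g$side <- g$side[names(g$side) != id]
  g$loop <- g$loop[names(g$loop) != id]
  invisible(g)
}

cg_is_conv_edge <- function(g, i) {
  g$kind[[g$e_n1[i]]] == "conv" && g$kind[[g$e_n2[i]]] == "conv"
}

cg_other_end <- function(g, i, n) if (g$e_n1[i] == n) g$e_n2[i] else g$e_n1[i]

cg_edges_of <- function(g, n, side = NULL) {
  ix <- g$inc[[n]]
  if (!is.null(side)) ix <- ix[g$e_side[ix] == side]
  ix
}

## number of side-edges a special node can still take (a region has two flanks)
cg_spec_capacity <- function(g, n) {
  used <- length(g$inc[[n]]) + sum(g$e_n1[g$inc[[n]]] == g$e_n2[g$inc[[n]]])
  2L - used
}

#' Build the common graph of two chromosome structures
#'
#' @param a,b `chrom_structure` objects with unique gene ids (resolve
#'   paralogs first, see [solve_paralog_matching()]).
#' @return a mutable common-graph environment of class `common_graph`.
#' @export
build_common_graph <- function(a, b) {
  ga <- structure_genes(a); gb <- structure_genes(b)
  common <- intersect(ga, gb)
  g <- cg_new()
  for (e in c(paste0(common, ":1", recycle0 = TRUE),
              paste0(common, ":2", recycle0 = TRUE)))
    cg_add_node(g, e, "conv")
  for (side in c("a", "b")) {
    s <- if (side == "a") a else b
    cnt <- 0L
    for (ch in s$chrs) {
      n <- length(ch$id)
      is_com <- ch$id %in% common
      ## element list: conventional extremity pairs or special run indices
      if (!any(is_com)) {
        cnt <- cnt + 1L
        nid <- sprintf("%s%d", toupper(side), cnt)
        cg_add_node(g, nid, "spec", side, signed_tokens(ch), loop = ch$circular)
        if (ch$circular) cg_add_edge(g, nid, nid, side, "R", "L")
        g$nspec <- g$nspec + 1L
        next
      }
      ## walk: produce sequence of elements in chromosome order
      elems <- list()
      i <- 1L
      while (i <= n) {
        if (is_com[i]) {
          elems[[length(elems) + 1L]] <- list(kind = "gene", i = i)
          i <- i + 1L
        } else {
          j <- i
          while (j < n && !is_com[j + 1L]) j <- j + 1L
          elems[[length(elems) + 1L]] <- list(kind = "run", ix = seq(i, j))
          i <- j + 1L
        }
      }
      ## circular wrap: merge a trailing run with a leading run
      wrap_run <- ch$circular && length(elems) > 1L &&
        elems[[1]]$kind == "run" && elems[[length(elems)]]$kind == "run"
      if (wrap_run) {
        elems[[1]]$ix <- c(elems[[length(elems)]]$ix, elems[[1]]$ix)
        elems[[length(elems)]] <- NULL
      }
      ## create special nodes
      ids <- character(length(elems))
      for (k in seq_along(elems)) {
        el <- elems[[k]]
        if (el$kind == "run") {
          cnt <- cnt + 1L
          nid <- sprintf("%s%d", toupper(side), cnt)
          tok <- signed_tokens(ch)[el$ix]
          cg_add_node(g, nid, "spec", side, tok)
          g$nspec <- g$nspec + 1L
          ids[k] <- nid
        }
      }
      ## connector extremities: for a gene element, entering extremity is
      ## tail (by sign), leaving is head; edges join leave(k) -> enter(k+1)
      leave <- function(k) {
        el <- elems[[k]]
        if (el$kind == "gene")
          list(n = ext_head(ch$id[el$i], ch$sign[el$i]), p = NA_character_)
        else list(n = ids[k], p = "R")
      }
      enter <- function(k) {
        el <- elems[[k]]
        if (el$kind == "gene")
          list(n = ext_tail(ch$id[el$i], ch$sign[el$i]), p = NA_character_)
        else list(n = ids[k], p = "L")
      }
      m <- length(elems)
      if (m > 1L)
        for (k in seq_len(m - 1L)) {
          l <- leave(k); e <- enter(k + 1L)
          cg_add_edge(g, l$n, e$n, side, l$p, e$p)
        }
      if (ch$circular) {
        l <- leave(m); e <- enter(1L)
        cg_add_edge(g, l$n, e$n, side, l$p, e$p)
      }
    }
  }
  class(g) <- c("common_graph", class(g))
  g
}

## --- components ------------------------------------------------------------

## returns list of components: list(nodes, shape, order)
## order: for a path, node sequence end-to-end; for a circle, cyclic sequence
cg_components <- function(g) {
  nodes <- names(g$kind)
  seen <- new.env(parent = emptyenv())
  comps <- list()
  for (start in nodes) {
    if (exists(start, envir = seen, inherits = FALSE)) next
    ## collect component by BFS
    stack <- start; members <- character(0)
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (exists(v, envir = seen, inherits = FALSE)) next
      assign(v, TRUE, envir = seen)
      members <- c(members, v)
      for (i in g$inc[[v]]) {
        o <- cg_other_end(g, i, v)
        if (!exists(o, envir = seen, inherits = FALSE)) stack <- c(stack, o)
      }
    }
    deg <- vapply(members, function(v)
      length(g$inc[[v]]) + sum(g$e_n1[g$inc[[v]]] == g$e_n2[g$inc[[v]]]), 0L)
    if (length(members) == 1L && deg[1] %in% c(0L, 2L) &&
        (deg[1] == 0L || any(g$e_n1[g$inc[[members]]] == g$e_n2[g$inc[[members]]]))) {
      shape <- if (deg[1] == 0L) "isolated" else "loop_node"
      comps[[length(comps) + 1L]] <- list(nodes = members, shape = shape,
                                          order = members, edges = g$inc[[members[1]]])
      next
    }
    ends <- members[deg == 1L]
    if (length(ends) == 0L) {
      ## circle: walk from the smallest node
      v0 <- min(members)
      ord <- v0; eord <- integer(0)
      prev_e <- -1L
      v <- v0
      repeat {
        es <- setdiff(g$inc[[v]], prev_e)
        i <- es[1]
        nxt <- cg_other_end(g, i, v)
        eord <- c(eord, i)
        if (nxt == v0) break
        ord <- c(ord, nxt)
        prev_e <- i; v <- nxt
      }
      comps[[length(comps) + 1L]] <- list(nodes = members, shape = "circle",
                                          order = ord, edges = eord)
    } else {
      v0 <- min(ends)
      ord <- v0; eord <- integer(0)
      prev_e <- -1L; v <- v0
      repeat {
        es <- setdiff(g$inc[[v]], prev_e)
        if (length(es) == 0L) break
        i <- es[1]
        nxt <- cg_other_end(g, i, v)
        eord <- c(eord, i); ord <- c(ord, nxt)
        prev_e <- i; v <- nxt
      }
      comps[[length(comps) + 1L]] <- list(nodes = members, shape = "path",
                                          order = ord, edges = eord)
    }
  }
  comps
}

## --- classification --------------------------------------------------------

comp_length <- function(g, comp) {
  if (comp$shape %in% c("isolated", "loop_node")) return(0L)
  internal_spec <- if (comp$shape == "circle") {
    sum(g$kind[comp$order] == "spec")
  } else {
    inner <- comp$order[-c(1L, length(comp$order))]
    sum(g$kind[inner] == "spec")
  }
  nconv <- sum(vapply(comp$edges, function(i) cg_is_conv_edge(g, i), TRUE))
  internal_spec + nconv
}

comp_is_final <- function(g, comp) {
  if (comp$shape == "isolated" && g$kind[[comp$nodes]] == "conv") return(TRUE)
  if (comp$shape == "circle" && length(comp$order) == 2L &&
      all(g$kind[comp$order] == "conv") &&
      length(comp$edges) == 2L && setequal(g$e_side[comp$edges], c("a", "b")))
    return(TRUE)
  FALSE
}

## classify one non-final component into the path/circle taxonomy
classify_component <- function(g, comp) {
  if (comp_is_final(g, comp)) return("final")
  ord <- comp$order
  kinds <- g$kind[ord]
  specs <- ord[kinds == "spec"]
  sides <- g$side[specs]
  has_a <- any(sides == "a"); has_b <- any(sides == "b")
  if (comp$shape == "loop_node")
    return(if (g$side[[comp$nodes]] == "a") "a_loop" else "loop")
  if (comp$shape == "isolated") {
    if (g$kind[[comp$nodes]] == "conv") return("final")
    return(if (g$side[[comp$nodes]] == "b") "2a'" else "2b'")
  }
  if (comp$shape == "circle") {
    if (!length(specs)) return("conv_circle")
    if (has_a && has_b) return("circle")
    return(if (has_a) "a-circle" else "b-circle")
  }
  ## paths
  L <- comp_length(g, comp)
  n <- length(ord)
  end1 <- ord[1]; end2 <- ord[n]
  end_spec <- c(g$kind[[end1]] == "spec", g$kind[[end2]] == "spec")
  h <- sum(end_spec)   # hanging edges
  odd <- L %% 2L == 1L
  end_side <- function(v, edge_i) {
    if (g$kind[[v]] == "spec") g$side[[v]] else g$e_side[edge_i]
  }
  s1 <- end_side(end1, comp$edges[1])
  s2 <- end_side(end2, comp$edges[length(comp$edges)])
  if (!length(specs)) return("conv_path")
  if (odd) {
    ## odd paths: a-path (conv ends carry a-edges, special ends are b-nodes)
    ## or b-path, by parity of the construction
    apathish <- all(c(if (!end_spec[1]) s1 == "a" else s1 == "b",
                      if (!end_spec[2]) s2 == "a" else s2 == "b"))
    if (apathish) {
      if (h == 1L) return("1a")
      if (h == 2L) return("2a")
      return(if (has_b) "3a" else "3a'")
    } else {
      if (h == 1L) return("1b")
      if (h == 2L) return("2b")
      return(if (has_a) "3b" else "3b'")
    }
  }
  ## even paths
  if (h == 0L) return("3")
  if (h == 2L) {
    if (length(comp$edges) == 2L && length(specs) == 2L) return("2'")
    return("2")
  }
  ## h == 1: subtype by the extreme special node's side
  ext_sp <- if (end_spec[1]) end1 else end2
  if (length(comp$edges) == 1L)
    return(if (g$side[[ext_sp]] == "a") "1'" else "1''")
  if (g$side[[ext_sp]] == "a") "1_a" else "1_b"
}

## aggregate view used by the combination tables
type_aggregate <- function(t) {
  switch(t,
    "2a'" = "2a", "3b'" = "3b", "1''" = "1_b", "2'" = "2",
    t)
}
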
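## ---------------------------------------------------------------------------
## The five-step transformation of the common graph into its final form,
## emitting a minimum-weight operation scenario.
##   Step 1  delete special a-loops;
##   Step 2  close regions of conventional edges into final 2-circles;
##   Step 3  combine paths (each action saves one operation and decrements
##            the number of special nodes);
##   Step 4  pair components so that deletions of b-nodes are replaced by
##            cheaper operations joining two b-nodes, then close paths into
##            circles;
##   Step 5  delete what remains.
## ---------------------------------------------------------------------------

## --- component inspection ---------------------------------------------------

comp_min_node <- function(comp) min(comp$nodes)

## conventional ends of a path with their marginal edge
comp_conv_ends <- function(g, comp) {
  if (comp$shape != "path") return(list())
  out <- list()
  n <- length(comp$order)
  for (k in c(1L, n)) {
    v <- comp$order[k]
    if (g$kind[[v]] == "conv") {
      ei <- comp$edges[if (k == 1L) 1L else length(comp$edges)]
      out[[length(out) + 1L]] <- list(node = v, edge = ei, side = g$e_side[ei])
    }
  }
  out
}

## special ends of a path (or the node itself when isolated)
comp_spec_ends <- function(g, comp) {
  if (comp$shape == "isolated") {
    v <- comp$nodes
    if (g$kind[[v]] == "spec")
      return(list(list(node = v, side = g$side[[v]], port = free_port(g, v)[1])))
    return(list())
  }
  if (comp$shape != "path") return(list())
  out <- list()
  n <- length(comp$order)
  for (k in c(1L, n)) {
    v <- comp$order[k]
    if (g$kind[[v]] == "spec")
      out[[length(out) + 1L]] <- list(node = v, side = g$side[[v]],
                                      port = free_port(g, v)[1])
  }
  out
}

comp_has_side_node <- function(g, comp, side) {
  any(vapply(comp$nodes, function(v)
    g$kind[[v]] == "spec" && g$side[[v]] == side, TRUE))
}

## --- engine component listing with deferred-choice override -----------------

engine_components <- function(st) {
  g <- st$g
  comps <- cg_components(g)
  entries <- list()
  pending_nodes <- lapply(st$pending, `[[`, "nodes")
  used_pending <- logical(length(st$pending))
  for (comp in comps) {
    if (comp_is_final(g, comp)) next
    pidx <- 0L
    for (q in seq_along(pending_nodes))
      if (any(comp$nodes %in% pending_nodes[[q]])) { pidx <- q; break }
    if (pidx > 0L) {
      if (!used_pending[pidx]) {
        used_pending[pidx] <- TRUE
        entries[[length(entries) + 1L]] <-
          list(type = "1_c", comp = NULL, pending = pidx,
               key = min(unlist(pending_nodes[[pidx]])))
      }
      next
    }
    entries[[length(entries) + 1L]] <-
      list(type = classify_component(g, comp), comp = comp, pending = 0L,
           key = comp_min_node(comp))
  }
  entries[order(vapply(entries, `[[`, "", "key"))]
}

find_entry <- function(st, marker) {
  for (e in engine_components(st))
    if (!is.null(e$comp) && marker %in% e$comp$nodes) return(e)
  NULL
}

## --- merge primitives -------------------------------------------------------

## options for cutting an external non-hanging edge of X and joining the
## freed special node to an extreme special node (or free conventional end)
## of Y
gather_cut_options <- function(st, Xe, Ye, side = NULL, target = "spec") {
  g <- st$g
  opts <- list()
  for (ce in comp_conv_ends(g, Xe$comp)) {
    eps <- edge_pts(g, ce$edge)
    Sp <- if (eps[[1]]$node == ce$node) eps[[2]] else eps[[1]]
    if (g$kind[[Sp$node]] != "spec") next   # leftover conventional edge
    s <- ce$side
    if (!is.null(side) && s != side) next
    if (target == "spec") {
      for (se in comp_spec_ends(g, Ye$comp)) {
        if (se$side != s || is.na(se$port)) next
        opts[[length(opts) + 1L]] <-
          list(edge = ce$edge, keep = Sp, tgt = pt(se$node, se$port),
               cut_side = s, key = paste(ce$node, se$node))
      }
    } else {
      for (te in comp_conv_ends(g, Ye$comp)) {
        if (te$side != if (s == "a") "b" else "a") next  # end missing side s
        opts[[length(opts) + 1L]] <-
          list(edge = ce$edge, keep = Sp, tgt = pt(te$node),
               cut_side = s, key = paste(ce$node, te$node))
      }
    }
  }
  opts[order(vapply(opts, `[[`, "", "key"))]
}

do_cut_join <- function(st, Xe, Ye, side = NULL, target = "spec") {
  opts <- gather_cut_options(st, Xe, Ye, side, target)
  if (!length(opts))
    stop("internal: no cut-join option for types ", Xe$type, "+", Ye$type)
  o <- opts[[1]]
  eng_sesqui(st, o$edge, o$keep, o$tgt)
  o$keep$node
}

do_join_ends <- function(st, Xe, Ye, side) {
  g <- st$g
  ux <- Filter(function(se) se$side == side && !is.na(se$port), comp_spec_ends(g, Xe$comp))
  uy <- Filter(function(se) se$side == side && !is.na(se$port), comp_spec_ends(g, Ye$comp))
  if (!length(ux) || !length(uy))
    stop("internal: no joinable ends for ", Xe$type, "+", Ye$type)
  u <- ux[[1]]; t <- uy[[1]]
  eng_join(st, pt(u$node, u$port), pt(t$node, t$port), side)
  u$node
}

do_conv_join_cut <- function(st, Xe, Ye, side_join) {
  g <- st$g
  miss <- if (side_join == "a") "b" else "a"
  xs <- Filter(function(ce) ce$side == miss, comp_conv_ends(g, Xe$comp))
  ys <- Filter(function(ce) ce$side == miss, comp_conv_ends(g, Ye$comp))
  if (!length(xs) || !length(ys))
    stop("internal: no conventional ends for ", Xe$type, "+", Ye$type)
  j <- eng_join(st, pt(xs[[1]]$node), pt(ys[[1]]$node), side_join)
  close_edge(st, j)
  xs[[1]]$node
}

## trim X at its extreme special a-node: detach [A]-x as a type-1' piece and
## join the node beyond x to Y's extreme special b-node
do_trim_join <- function(st, Xe, Ye) {
  g <- st$g
  aends <- Filter(function(se) se$side == "a", comp_spec_ends(g, Xe$comp))
  if (!length(aends)) stop("internal: trim needs an extreme a-node on ", Xe$type)
  A <- aends[[1]]$node
  ha <- g$inc[[A]][1]
  x <- cg_other_end(g, ha, A)
  e2 <- setdiff(g$inc[[x]], ha)
  stopifnot(length(e2) == 1L)
  eps <- edge_pts(g, e2)
  Z <- if (eps[[1]]$node == x) eps[[2]] else eps[[1]]
  bends <- Filter(function(se) se$side == "b", comp_spec_ends(g, Ye$comp))
  if (!length(bends)) stop("internal: trim target needs an extreme b-node")
  T <- bends[[1]]
  eng_sesqui(st, e2, Z, pt(T$node, T$port))
  list(marker = if (g$kind[[Z$node]] == "spec") Z$node else T$node, one_prime = A)
}

do_loop_merge <- function(st, loopE, tE) {
  g <- st$g
  L <- loopE$comp$nodes
  le <- g$inc[[L]][1]
  bnodes <- sort(Filter(function(v) g$kind[[v]] == "spec" && g$side[[v]] == "b",
                        tE$comp$nodes))
  T <- bnodes[[1]]
  et <- cg_edges_of(g, T)
  if (!length(et)) {
    eng_sesqui(st, le, pt(L, "R"), pt(T, "L"))
  } else if (g$e_n1[et[1]] == g$e_n2[et[1]]) {
    ## t is itself a special loop: double merging the two loop nodes
    eng_dcj(st, le, et[1], list(pt(L, "R"), pt(T, "L")), list(pt(L, "L"), pt(T, "R")))
  } else {
    et <- et[1]
    q <- edge_port(g, et, T)
    eps <- edge_pts(g, et)
    u <- if (eps[[1]]$node == T) eps[[2]] else eps[[1]]
    eng_dcj(st, le, et, list(pt(L, "R"), pt(T, q)), list(pt(L, "L"), u))
  }
  invisible(L)
}

## splice a circle with a b-node into a component holding both a- and b-nodes
do_circle_splice <- function(st, circE, tE) {
  g <- st$g
  cb <- sort(Filter(function(v) g$kind[[v]] == "spec" && g$side[[v]] == "b",
                    circE$comp$nodes))
  Bc <- cb[[1]]
  ec <- cg_edges_of(g, Bc)[1]
  pc <- edge_port(g, ec, Bc)
  eps <- edge_pts(g, ec)
  v <- if (eps[[1]]$node == Bc) eps[[2]] else eps[[1]]
  ## choose the flank of a b-node of t directed towards an a-node
  pick <- pick_flank_towards_a(g, tE$comp)
  jj <- eng_dcj(st, ec, pick$edge,
                list(pt(Bc, pc), pt(pick$bnode, pick$port)),
                list(v, pick$u))
  ## the reconnecting edge is conventional; cut it out
  if (cg_is_conv_edge(g, jj[2])) close_edge(st, jj[2])
  invisible(pick$bnode)
}

pick_flank_towards_a <- function(g, comp) {
  ord <- comp$order
  n <- length(ord)
  is_b <- vapply(ord, function(v) g$kind[[v]] == "spec" && g$side[[v]] == "b", TRUE)
  is_a <- vapply(ord, function(v) g$kind[[v]] == "spec" && g$side[[v]] == "a", TRUE)
  cands <- list()
  for (k in which(is_b)) {
    for (dir in c(1L, -1L)) {
      ## walk from position k in direction dir, look for an a-node
      pos <- k; steps <- 0L; found <- FALSE
      repeat {
        pos <- pos + dir
        if (comp$shape == "circle") pos <- ((pos - 1L) %% n) + 1L
        else if (pos < 1L || pos > n) break
        steps <- steps + 1L
        if (steps > n) break
        if (is_a[pos]) { found <- TRUE; break }
        if (is_b[pos]) break
      }
      if (!found) next
      ## edge leaving ord[k] in direction dir
      ei <- if (dir == 1L) {
        if (k < n) comp$edges[k] else comp$edges[n]       # circle wrap
      } else {
        if (k > 1L) comp$edges[k - 1L] else {
          if (comp$shape == "circle") comp$edges[n] else NA_integer_
        }
      }
      if (is.na(ei)) next
      B <- ord[k]
      q <- edge_port(g, ei, B)
      eps <- edge_pts(g, ei)
      u <- if (eps[[1]]$node == B) eps[[2]] else eps[[1]]
      if (g$kind[[u$node]] != "conv") next
      cands[[length(cands) + 1L]] <- list(bnode = B, edge = ei, port = q, u = u,
                                          key = paste(B, u$node))
    }
  }
  if (!length(cands)) stop("internal: no flank towards an a-node")
  cands[order(vapply(cands, `[[`, "", "key"))][[1]]
}

## --- deferred choice (type 1_c) --------------------------------------------

make_pending <- function(st, Xe, Ye, kind) {
  ## kind "31": X of type 1a, Y of type 1b; kind "33": X of type 2, Y of 3
  g <- st$g
  if (kind == "31") {
    oa <- gather_cut_options(st, Xe, Ye, side = "a")  # cut in the 1a: yields 1_b
    ob <- gather_cut_options(st, Ye, Xe, side = "b")  # cut in the 1b: yields 1_a
  } else {
    oa <- gather_cut_options(st, Ye, Xe, side = "a")  # cut a-edge of the 3-path
    ob <- gather_cut_options(st, Ye, Xe, side = "b")  # cut b-edge of the 3-path
  }
  if (!length(oa) || !length(ob))
    stop("internal: cannot defer ", Xe$type, "+", Ye$type)
  st$pending[[length(st$pending) + 1L]] <-
    list(nodes = c(Xe$comp$nodes, Ye$comp$nodes),
         opts = list("1_b" = oa[[1]], "1_a" = ob[[1]]))
  invisible(st)
}

resolve_pending <- function(st, pidx, result) {
  p <- st$pending[[pidx]]
  o <- p$opts[[result]]
  eng_sesqui(st, o$edge, o$keep, o$tgt)
  st$pending[[pidx]] <- NULL
  o$keep$node
}
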
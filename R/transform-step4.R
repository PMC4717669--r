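## ---------------------------------------------------------------------------
## Step 4 (pairing that replaces b-node deletions by joins of two b-nodes),
## the path closures of action 4.24, and step 5 cleanup.
## ---------------------------------------------------------------------------

## wildcard slots: "TWB" = any component with a b-node, "TWAB" = with both.
## In the unprimed regime the rule tables name aggregated types (2a covers
## 2a', 3b covers 3b', 1_b covers 1'', 2 covers 2'); the primed regime lists
## the degenerate variants explicitly and matches exactly.
slot_matches <- function(entry, slot, g, aggregate = FALSE) {
  if (slot == "1_c") return(entry$type == "1_c")
  if (is.null(entry$comp)) return(FALSE)
  if (slot == "TWB")
    return(!entry$type %in% c("final") &&
             comp_has_side_node(g, entry$comp, "b"))
  if (slot == "TWAB")
    return(comp_has_side_node(g, entry$comp, "b") &&
             comp_has_side_node(g, entry$comp, "a"))
  if (aggregate && slot %in% c("2a", "3b", "1_b", "2"))
    return(type_aggregate(entry$type) == slot)
  entry$type == slot
}

match_exact <- function(entries, lhs, g, aggregate = FALSE) {
  used <- logical(length(entries))
  picked <- vector("list", length(lhs))
  for (k in seq_along(lhs)) {
    found <- FALSE
    for (j in seq_along(entries)) {
      if (used[j]) next
      if (slot_matches(entries[[j]], lhs[k], g, aggregate)) {
        used[j] <- TRUE; picked[[k]] <- entries[[j]]; found <- TRUE; break
      }
    }
    if (!found) return(NULL)
  }
  picked
}

resolve_entry <- function(st, entry, result) {
  m <- resolve_pending(st, entry$pending, result)
  find_entry(st, m)
}

step4_rules <- function(primed) {
  cj <- function(from, to, side = NULL, target = "spec") function(st, es)
    do_cut_join(st, es[[from]], es[[to]], side = side, target = target)
  jn <- function(a, b, side) function(st, es)
    do_join_ends(st, es[[a]], es[[b]], side)
  cvc <- function(a, b, side_join) function(st, es)
    do_conv_join_cut(st, es[[a]], es[[b]], side_join)
  trim <- function(x, y) function(st, es) {
    r <- do_trim_join(st, es[[x]], es[[y]])
    r$marker
  }
  res_cj <- function(pend_slot, other_slot, result, from_pending, side = NULL)
    function(st, es) {
      ne <- resolve_entry(st, es[[pend_slot]], result)
      other <- find_entry(st, es[[other_slot]]$key)  # refresh
      if (from_pending) do_cut_join(st, ne, other, side = side)
      else do_cut_join(st, other, ne, side = side)
    }
  alt <- function(...) list(...)
  rule <- function(lhs, fn) list(lhs = lhs, fn = fn)

  g41 <- alt(rule(c("loop", "TWB"), function(st, es) do_loop_merge(st, es[[1]], es[[2]])))
  g42 <- alt(rule(c("circle", "TWAB"), function(st, es) do_circle_splice(st, es[[1]], es[[2]])))
  g424 <- NULL  # closures handled separately

  if (!primed) {
    list(
      g41, g42,
      alt(rule(c("2a", "2b"), trim(2, 1))),
      alt(rule(c("3a", "3b"), cj(1, 2, target = "conv"))),
      alt(rule(c("2a", "3"), cj(2, 1, side = "b")),
          rule(c("2b", "3"), cj(2, 1, side = "a"))),
      alt(rule(c("3a", "2"), cj(1, 2)), rule(c("3b", "2"), cj(1, 2))),
      alt(rule(c("2a'", "2a"), jn(1, 2, "b"))),
      alt(rule(c("3a", "3a"), cvc(1, 2, "b")), rule(c("3b", "3b"), cvc(1, 2, "a"))),
      alt(rule(c("1a", "2a"), jn(1, 2, "b")), rule(c("1b", "2b"), jn(1, 2, "a"))),
      alt(rule(c("1a", "3a"), cvc(1, 2, "b")), rule(c("1b", "3b"), cvc(1, 2, "a"))),
      alt(rule(c("2a", "2"), jn(1, 2, "b")), rule(c("2b", "2"), jn(1, 2, "a"))),
      alt(rule(c("3a", "3"), cvc(1, 2, "b")), rule(c("3b", "3"), cvc(1, 2, "a"))),
      alt(rule(c("2", "2"), trim(1, 2))),
      alt(rule(c("3", "3"), cj(1, 2, side = "a", target = "conv"))),
      alt(rule(c("1_a", "1_a"), cj(1, 2)), rule(c("1_b", "1_b"), cj(1, 2)),
          rule(c("1_b", "1_c"), res_cj(2, 1, "1_b", from_pending = TRUE))),
      alt(rule(c("1a", "1_b"), cj(2, 1)), rule(c("1b", "1_a"), cj(2, 1)),
          rule(c("1a", "1_c"), res_cj(2, 1, "1_b", from_pending = TRUE))),
      alt(rule(c("1a", "1_a"), cj(1, 2)), rule(c("1b", "1_b"), cj(1, 2)),
          rule(c("1b", "1_c"), res_cj(2, 1, "1_b", from_pending = FALSE))),
      alt(rule(c("2a", "1_b"), cj(2, 1)), rule(c("2b", "1_a"), cj(2, 1)),
          rule(c("2a", "1_c"), res_cj(2, 1, "1_b", from_pending = TRUE))),
      alt(rule(c("3a", "1_a"), cj(1, 2)), rule(c("3b", "1_b"), cj(1, 2)),
          rule(c("3b", "1_c"), res_cj(2, 1, "1_b", from_pending = FALSE))),
      alt(rule(c("2", "1_a"), cj(2, 1)), rule(c("2", "1_b"), cj(2, 1)),
          rule(c("2", "1_c"), res_cj(2, 1, "1_b", from_pending = TRUE))),
      alt(rule(c("3", "1_a"), cj(1, 2, side = "a")),
          rule(c("3", "1_b"), cj(1, 2, side = "b")),
          rule(c("3", "1_c"), res_cj(2, 1, "1_b", from_pending = FALSE, side = "b"))),
      alt(rule(c("1_a", "1_c"), res_cj(2, 1, "1_a", from_pending = TRUE)),
          rule(c("1b", "1_c"), res_cj(2, 1, "1_a", from_pending = TRUE)),
          rule(c("1a", "1_c"), res_cj(2, 1, "1_a", from_pending = FALSE)),
          rule(c("2b", "1_c"), res_cj(2, 1, "1_a", from_pending = TRUE)),
          rule(c("3a", "1_c"), res_cj(2, 1, "1_a", from_pending = FALSE)))
    )
  } else {
    list(
      g41, g42,
      alt(rule(c("2a'", "2b"), trim(2, 1))),
      alt(rule(c("3a", "3b'"), cj(1, 2, target = "conv"))),
      alt(rule(c("2a'", "3"), cj(2, 1, side = "b"))),
      alt(rule(c("3a", "2'"), cj(1, 2)), rule(c("3b'", "2"), cj(1, 2))),
      alt(rule(c("2a'", "2a"), jn(1, 2, "b"))),
      alt(rule(c("3b'", "3b"), cvc(1, 2, "a"))),
      alt(rule(c("1a", "2a'"), jn(1, 2, "b"))),
      alt(rule(c("1b", "3b'"), cvc(1, 2, "a"))),
      alt(rule(c("2a'", "2"), jn(1, 2, "b")), rule(c("2a", "2'"), jn(1, 2, "b")),
          rule(c("2b", "2'"), jn(1, 2, "a"))),
      alt(rule(c("3b'", "3"), cvc(1, 2, "a"))),
      alt(rule(c("2'", "2"), trim(1, 2))),
      alt(rule(c("1''", "1_b"), cj(2, 1)),
          rule(c("1''", "1_c"), res_cj(2, 1, "1_b", from_pending = TRUE))),
      alt(rule(c("1a", "1''"), cj(2, 1))),
      alt(rule(c("1b", "1''"), cj(1, 2))),
      alt(rule(c("2a'", "1_b"), cj(2, 1)), rule(c("2a", "1''"), cj(2, 1)),
          rule(c("2a'", "1_c"), res_cj(2, 1, "1_b", from_pending = TRUE))),
      alt(rule(c("3b'", "1_b"), cj(1, 2)), rule(c("3b", "1''"), cj(1, 2)),
          rule(c("3b'", "1_c"), res_cj(2, 1, "1_b", from_pending = FALSE))),
      alt(rule(c("2'", "1_a"), cj(2, 1)), rule(c("2'", "1_b"), cj(2, 1)),
          rule(c("2", "1''"), cj(2, 1)),
          rule(c("2'", "1_c"), res_cj(2, 1, "1_b", from_pending = TRUE))),
      alt(rule(c("3", "1''"), cj(1, 2, side = "b")))
    )
  }
}

step4 <- function(st) {
  st$phase <- "s4"
  primed <- !(op_weight(st$w, "double") > op_weight(st$w, "sesqui"))
  key <- if (primed) "s4p" else "s4u"
  if (is.null(.rules_cache[[key]])) .rules_cache[[key]] <- step4_rules(primed)
  groups <- .rules_cache[[key]]
  for (group in groups) {
    repeat {
      entries <- engine_components(st)
      applied <- FALSE
      for (r in group) {
        es <- match_exact(entries, r$lhs, st$g, aggregate = !primed)
        if (is.null(es)) next
        r$fn(st, es)
        applied <- TRUE
        break
      }
      if (!applied) break
    }
  }
  ## consolidate isolated special b-nodes: inserting their regions as one
  ## chromosome and cutting it apart replaces b-node deletions by joins,
  ## worthwhile whenever the cut is no dearer than the insertion
  if (op_weight(st$w, "cut") <= op_weight(st$w, "ins_b")) {
    repeat {
      entries <- engine_components(st)
      iso <- Filter(function(e) e$type == "2a'", entries)
      if (length(iso) < 2L) break
      do_join_ends(st, iso[[1]], iso[[2]], "b")
    }
  }
  if (!primed) {
    ## 4.23: resolve remaining deferred choices to c = b and pair them
    repeat {
      entries <- engine_components(st)
      pend <- Filter(function(e) e$type == "1_c", entries)
      if (!length(pend)) break
      resolve_entry(st, pend[[1]], "1_b")
    }
    repeat {
      entries <- engine_components(st)
      bs <- Filter(function(e) e$type == "1_b", entries)
      if (length(bs) < 2L) break
      do_cut_join(st, bs[[1]], bs[[2]])
    }
  }
  ## 4.24: close paths with a non-hanging edge into circles
  repeat {
    entries <- engine_components(st)
    closable <- Filter(function(e)
      e$type %in% c("2a", "2b", "3a", "3b", "1_a", "1_b", "1_c", "2",
                    "1a", "1b", "3"), entries)
    if (!length(closable)) break
    close_component(st, closable[[1]])
  }
  ## ... then execute step 4.2 again
  repeat {
    entries <- engine_components(st)
    es <- match_exact(entries, c("circle", "TWAB"), st$g)
    if (is.null(es)) break
    do_circle_splice(st, es[[1]], es[[2]])
  }
  invisible(st)
}

## close one path into a circle (action 4.24)
close_component <- function(st, e) {
  g <- st$g
  ty <- e$type
  if (ty == "1_c") {
    ne <- resolve_entry(st, e, "1_b")
    return(close_component(st, ne))
  }
  if (ty %in% c("2a", "2b")) {
    side <- if (ty == "2a") "b" else "a"
    ends <- Filter(function(se) se$side == side, comp_spec_ends(g, e$comp))
    stopifnot(length(ends) == 2L)
    eng_join(st, pt(ends[[1]]$node, ends[[1]]$port),
             pt(ends[[2]]$node, ends[[2]]$port), side)
    return(invisible(st))
  }
  if (ty %in% c("3a", "3b")) {
    side <- if (ty == "3a") "b" else "a"
    ces <- comp_conv_ends(g, e$comp)
    stopifnot(length(ces) == 2L)
    j <- eng_join(st, pt(ces[[1]]$node), pt(ces[[2]]$node), side)
    close_edge(st, j)
    return(invisible(st))
  }
  if (ty %in% c("1_a", "1_b")) {
    do_cut_join(st, e, e)
    return(invisible(st))
  }
  if (ty == "2") {
    r <- do_trim_join(st, e, e)
    eng_delnode(st, r$one_prime)
    return(invisible(st))
  }
  if (ty %in% c("1a", "1b")) {
    side <- if (ty == "1a") "b" else "a"
    sp <- comp_spec_ends(g, e$comp)[[1]]
    ha <- g$inc[[sp$node]][1]
    u <- cg_other_end(g, ha, sp$node)
    ce <- comp_conv_ends(g, e$comp)[[1]]
    stopifnot(u != ce$node)
    eng_sesqui(st, ha, pt(u), pt(ce$node))
    return(invisible(st))
  }
  if (ty == "3") {
    do_cut_join(st, e, e, side = "a", target = "conv")
    return(invisible(st))
  }
  stop("internal: cannot close component of type ", ty)
}

## --- step 5 ----------------------------------------------------------------

step5 <- function(st) {
  st$phase <- "s5"
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 10000L) stop("internal: step 5 does not terminate")
    g <- st$g
    entries <- engine_components(st)
    if (!length(entries)) break
    e <- entries[[1]]
    if (e$type %in% c("loop", "a_loop", "2a'", "2b'")) {
      eng_delnode(st, e$comp$nodes)
      next
    }
    comp <- e$comp
    if (is.null(comp)) stop("internal: unresolved deferred component in step 5")
    if (comp$shape == "path") {
      sp <- comp$order[g$kind[comp$order] == "spec"]
      if (length(sp)) {
        ends <- comp$order[c(1L, length(comp$order))]
        endsp <- intersect(ends, sp)
        eng_delnode(st, if (length(endsp)) sort(endsp)[1] else sort(sp)[1])
        next
      }
      ## conventional remnants: close like step 2
      ne <- length(comp$edges)
      close_edge(st, comp$edges[min(2L, ne)])
      next
    }
    if (comp$shape == "circle") {
      reduce_circle_once(st, e)
      next
    }
    stop("internal: unexpected component in step 5: ", e$type)
  }
  invisible(st)
}

reduce_circle_once <- function(st, e) {
  g <- st$g
  comp <- e$comp
  L <- comp_length(g, comp)
  ord <- comp$order
  n <- length(ord)
  is_b <- vapply(ord, function(v) g$kind[[v]] == "spec" && g$side[[v]] == "b", TRUE)
  is_a <- vapply(ord, function(v) g$kind[[v]] == "spec" && g$side[[v]] == "a", TRUE)
  if (L <= 2L) {
    specs <- ord[is_a | is_b]
    aa <- ord[is_a]
    eng_delnode(st, if (length(aa)) sort(aa)[1] else sort(specs)[1])
    return(invisible(st))
  }
  for (side in c("b", "a")) {
    isx <- if (side == "b") is_b else is_a
    if (sum(isx) >= 2L) {
      ## cut out the segment between two consecutive side-nodes, merging them
      ks <- which(isx)
      k1 <- ks[1]
      k2 <- ks[which(ks > k1)[1]]
      if (is.na(k2)) k2 <- ks[2]
      e1 <- comp$edges[k1]                 # edge leaving ord[k1] forwards
      e2 <- comp$edges[if (k2 > 1L) k2 - 1L else n]
      B1 <- ord[k1]; B2 <- ord[k2]
      p1 <- edge_port(g, e1, B1); p2 <- edge_port(g, e2, B2)
      x <- cg_other_end(g, e1, B1); y <- cg_other_end(g, e2, B2)
      stopifnot(x != y)
      eng_dcj(st, e1, e2, list(pt(B1, p1), pt(B2, p2)), list(pt(x), pt(y)))
      return(invisible(st))
    }
  }
  conv <- comp$edges[vapply(comp$edges, function(i) cg_is_conv_edge(g, i), TRUE)]
  if (length(conv)) {
    close_edge(st, conv[1])
    return(invisible(st))
  }
  stop("internal: irreducible circle")
}
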
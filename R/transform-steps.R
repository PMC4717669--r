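## ---------------------------------------------------------------------------
## Steps 1-5 of the transformation, the combination rule tables of steps 3
## and 4, and the public transform_to_final().
## ---------------------------------------------------------------------------

## --- step 1: delete special a-loops ----------------------------------------

step1 <- function(st) {
  st$phase <- "s1"
  repeat {
    g <- st$g
    loops <- sort(names(g$kind)[vapply(names(g$kind), function(v)
      g$kind[[v]] == "spec" && g$side[[v]] == "a" &&
        any(g$e_n1[g$inc[[v]]] == g$e_n2[g$inc[[v]]]), TRUE)])
    if (!length(loops)) break
    eng_delnode(st, loops[1])
  }
  invisible(st)
}

## --- step 2: close regions of conventional edges ---------------------------

## a conventional edge is eligible unless it already lies in a final 2-circle
## or is the single leftover edge of an odd region bounded by special nodes
step2_pick <- function(st) {
  g <- st$g
  inner_first <- op_weight(st$w, "double") <= op_weight(st$w, "sesqui")
  for (e in engine_components(st)) {
    comp <- e$comp
    if (is.null(comp) || !comp$shape %in% c("path", "circle")) next
    ne <- length(comp$edges)
    conv <- vapply(comp$edges, function(i) cg_is_conv_edge(g, i), TRUE)
    if (!any(conv)) next
    if (comp$shape == "circle" && all(conv)) {
      if (ne == 2L) next                       # already final
      return(comp$edges[2])
    }
    ## maximal runs of conventional edges along the path/circle
    idx <- seq_len(ne)
    if (comp$shape == "circle") {
      ## rotate so a non-conventional edge comes last
      k <- which(!conv)[1]
      rot <- c(seq_len(ne)[-seq_len(k)], seq_len(k))
      idx <- idx[rot]; conv <- conv[rot]
    }
    r <- rle(conv)
    hi <- cumsum(r$lengths); lo <- hi - r$lengths + 1L
    for (ri in which(r$values)) {
      run <- comp$edges[idx[lo[ri]:hi[ri]]]
      l <- length(run)
      free_lo <- comp$shape == "path" && idx[lo[ri]] == 1L
      free_hi <- comp$shape == "path" && idx[hi[ri]] == ne
      if (l == 1L) {
        if (free_lo || free_hi) return(run[1])
        next                                    # odd leftover stays
      }
      if (inner_first) return(run[2])
      if (free_lo) return(run[1])
      if (free_hi) return(run[l])
      return(run[2])
    }
  }
  NULL
}

step2 <- function(st) {
  st$phase <- "s2"
  repeat {
    e <- step2_pick(st)
    if (is.null(e)) break
    close_edge(st, e)
  }
  invisible(st)
}

## --- step 3 rule table ------------------------------------------------------

## match lhs (aggregate type names) against entries; returns entry list or NULL
match_types <- function(entries, lhs, aggregate = TRUE) {
  used <- logical(length(entries))
  picked <- vector("list", length(lhs))
  for (k in seq_along(lhs)) {
    found <- FALSE
    for (j in seq_along(entries)) {
      if (used[j]) next
      ty <- entries[[j]]$type
      if (aggregate) ty <- type_aggregate(ty)
      if (ty == lhs[k]) { used[j] <- TRUE; picked[[k]] <- entries[[j]]; found <- TRUE; break }
    }
    if (!found) return(NULL)
  }
  picked
}

step3_rules <- function() {
  cj <- function(from, to, side = NULL) function(st, es)
    do_cut_join(st, es[[from]], es[[to]], side = side)
  jn <- function(a, b, side) function(st, es)
    do_join_ends(st, es[[a]], es[[b]], side)
  def31 <- function(st, es) make_pending(st, es[[1]], es[[2]], "31")
  def33 <- function(st, es) make_pending(st, es[[1]], es[[2]], "33")
  seq2 <- function(f1, f2) function(st, es) { m <- f1(st, es); f2(st, es, m) }
  list(
    list(lhs = c("1a", "1b"), fn = def31),
    list(lhs = c("2a", "3b"), fn = cj(2, 1)),
    list(lhs = c("2b", "3a"), fn = cj(2, 1)),
    list(lhs = c("2b'", "3a"), fn = cj(2, 1)),
    list(lhs = c("2b", "3a'"), fn = cj(2, 1)),
    list(lhs = c("2b'", "3a'"), fn = cj(2, 1)),
    list(lhs = c("2", "3"), fn = def33),
    ## 3.4 family
    list(lhs = c("1b", "2a", "3"), fn = function(st, es) {
      m <- do_cut_join(st, es[[1]], es[[2]])
      make_pending(st, find_entry(st, m), es[[3]], "33")
    }),
    list(lhs = c("1a", "2b", "3"), fn = function(st, es) {
      m <- do_cut_join(st, es[[1]], es[[2]])
      make_pending(st, find_entry(st, m), es[[3]], "33")
    }),
    list(lhs = c("1a", "2b'", "3"), fn = function(st, es) {
      m <- do_cut_join(st, es[[1]], es[[2]])
      make_pending(st, find_entry(st, m), es[[3]], "33")
    }),
    ## 3.5 family
    list(lhs = c("1a", "3b", "2"), fn = function(st, es) {
      m <- do_cut_join(st, es[[2]], es[[1]])
      make_pending(st, es[[3]], find_entry(st, m), "33")
    }),
    list(lhs = c("1b", "3a", "2"), fn = function(st, es) {
      m <- do_cut_join(st, es[[2]], es[[1]])
      make_pending(st, es[[3]], find_entry(st, m), "33")
    }),
    list(lhs = c("1b", "3a'", "2"), fn = function(st, es) {
      m <- do_cut_join(st, es[[2]], es[[1]])
      make_pending(st, es[[3]], find_entry(st, m), "33")
    }),
    list(lhs = c("1a", "2"), fn = cj(1, 2)),
    list(lhs = c("1b", "2"), fn = cj(1, 2)),
    list(lhs = c("1a", "3"), fn = cj(2, 1, side = "b")),
    list(lhs = c("1b", "3"), fn = cj(2, 1, side = "a")),
    ## 3.8 family
    list(lhs = c("1a", "1a", "2b", "3b"), fn = function(st, es) {
      m1 <- do_cut_join(st, es[[1]], es[[3]])
      m2 <- do_cut_join(st, es[[4]], es[[2]])
      make_pending(st, find_entry(st, m1), find_entry(st, m2), "33")
    }),
    list(lhs = c("1a", "1a", "2b'", "3b"), fn = function(st, es) {
      m1 <- do_cut_join(st, es[[1]], es[[3]])
      m2 <- do_cut_join(st, es[[4]], es[[2]])
      make_pending(st, find_entry(st, m1), find_entry(st, m2), "33")
    }),
    list(lhs = c("1b", "1b", "2a", "3a"), fn = function(st, es) {
      m1 <- do_cut_join(st, es[[1]], es[[3]])
      m2 <- do_cut_join(st, es[[4]], es[[2]])
      make_pending(st, find_entry(st, m1), find_entry(st, m2), "33")
    }),
    list(lhs = c("1b", "1b", "2a", "3a'"), fn = function(st, es) {
      m1 <- do_cut_join(st, es[[1]], es[[3]])
      m2 <- do_cut_join(st, es[[4]], es[[2]])
      make_pending(st, find_entry(st, m1), find_entry(st, m2), "33")
    }),
    ## 3.9 family
    list(lhs = c("1a", "1a", "2b"), fn = function(st, es) {
      m <- do_join_ends(st, es[[1]], es[[2]], "b")
      do_cut_join(st, find_entry(st, m), es[[3]])
    }),
    list(lhs = c("1a", "1a", "2b'"), fn = function(st, es) {
      m <- do_join_ends(st, es[[1]], es[[2]], "b")
      do_cut_join(st, find_entry(st, m), es[[3]])
    }),
    list(lhs = c("1b", "1b", "2a"), fn = function(st, es) {
      m <- do_join_ends(st, es[[1]], es[[2]], "a")
      do_cut_join(st, find_entry(st, m), es[[3]])
    }),
    ## 3.10 family
    list(lhs = c("1a", "1a", "3b"), fn = function(st, es) {
      m <- do_cut_join(st, es[[3]], es[[1]])
      do_cut_join(st, find_entry(st, m), es[[2]], side = "b")
    }),
    list(lhs = c("1b", "1b", "3a"), fn = function(st, es) {
      m <- do_cut_join(st, es[[3]], es[[1]])
      do_cut_join(st, find_entry(st, m), es[[2]], side = "a")
    }),
    list(lhs = c("1b", "1b", "3a'"), fn = function(st, es) {
      m <- do_cut_join(st, es[[3]], es[[1]])
      do_cut_join(st, find_entry(st, m), es[[2]], side = "a")
    }),
    list(lhs = c("1a", "1a"), fn = jn(1, 2, "b")),
    list(lhs = c("1b", "1b"), fn = jn(1, 2, "a")),
    list(lhs = c("1a", "2b"), fn = cj(1, 2)),
    list(lhs = c("1a", "2b'"), fn = cj(1, 2)),
    list(lhs = c("1b", "2a"), fn = cj(1, 2)),
    list(lhs = c("1a", "3b"), fn = cj(2, 1)),
    list(lhs = c("1b", "3a"), fn = cj(2, 1)),
    list(lhs = c("1b", "3a'"), fn = cj(2, 1)),
    ## 3.14 family
    list(lhs = c("2a", "2b", "3", "3"), fn = function(st, es) {
      m1 <- do_cut_join(st, es[[3]], es[[2]], side = "a")
      m2 <- do_cut_join(st, find_entry(st, m1), es[[1]])
      make_pending(st, find_entry(st, m2), es[[4]], "33")
    }),
    list(lhs = c("2a", "2b'", "3", "3"), fn = function(st, es) {
      m1 <- do_cut_join(st, es[[3]], es[[2]], side = "a")
      m2 <- do_cut_join(st, find_entry(st, m1), es[[1]])
      make_pending(st, find_entry(st, m2), es[[4]], "33")
    }),
    ## 3.15 family
    list(lhs = c("3a", "3b", "2", "2"), fn = function(st, es) {
      m1 <- do_cut_join(st, es[[2]], es[[3]])
      m2 <- do_cut_join(st, es[[1]], find_entry(st, m1))
      make_pending(st, es[[4]], find_entry(st, m2), "33")
    }),
    list(lhs = c("3a'", "3b", "2", "2"), fn = function(st, es) {
      m1 <- do_cut_join(st, es[[2]], es[[3]])
      m2 <- do_cut_join(st, es[[1]], find_entry(st, m1))
      make_pending(st, es[[4]], find_entry(st, m2), "33")
    }),
    ## 3.16 family
    list(lhs = c("2a", "3", "3"), fn = function(st, es) {
      m <- do_cut_join(st, es[[2]], es[[1]], side = "b")
      do_cut_join(st, es[[3]], find_entry(st, m), side = "b")
    }),
    list(lhs = c("2b", "3", "3"), fn = function(st, es) {
      m <- do_cut_join(st, es[[2]], es[[1]], side = "a")
      do_cut_join(st, es[[3]], find_entry(st, m), side = "a")
    }),
    list(lhs = c("2b'", "3", "3"), fn = function(st, es) {
      m <- do_cut_join(st, es[[2]], es[[1]], side = "a")
      do_cut_join(st, es[[3]], find_entry(st, m), side = "a")
    }),
    ## 3.17 family
    list(lhs = c("3b", "2", "2"), fn = function(st, es) {
      m <- do_cut_join(st, es[[1]], es[[2]])
      do_cut_join(st, find_entry(st, m), es[[3]])
    }),
    list(lhs = c("3a", "2", "2"), fn = function(st, es) {
      m <- do_cut_join(st, es[[1]], es[[2]])
      do_cut_join(st, find_entry(st, m), es[[3]])
    }),
    list(lhs = c("3a'", "2", "2"), fn = function(st, es) {
      m <- do_cut_join(st, es[[1]], es[[2]])
      do_cut_join(st, find_entry(st, m), es[[3]])
    }),
    ## 3.18 family
    list(lhs = c("2a", "2b", "3"), fn = function(st, es) {
      m <- do_cut_join(st, es[[3]], es[[2]], side = "a")
      do_cut_join(st, find_entry(st, m), es[[1]])
    }),
    list(lhs = c("2a", "2b'", "3"), fn = function(st, es) {
      m <- do_cut_join(st, es[[3]], es[[2]], side = "a")
      do_cut_join(st, find_entry(st, m), es[[1]])
    }),
    ## 3.19 family
    list(lhs = c("3a", "3b", "2"), fn = function(st, es) {
      m <- do_cut_join(st, es[[2]], es[[3]])
      do_cut_join(st, es[[1]], find_entry(st, m))
    }),
    list(lhs = c("3a'", "3b", "2"), fn = function(st, es) {
      m <- do_cut_join(st, es[[2]], es[[3]])
      do_cut_join(st, es[[1]], find_entry(st, m))
    })
  )
}

.rules_cache <- new.env(parent = emptyenv())

step3 <- function(st) {
  st$phase <- "s3"
  if (is.null(.rules_cache$s3)) .rules_cache$s3 <- step3_rules()
  rules <- .rules_cache$s3
  repeat {
    entries <- engine_components(st)
    applied <- FALSE
    for (rule in rules) {
      es <- match_types(entries, rule$lhs, aggregate = TRUE)
      if (is.null(es)) next
      rule$fn(st, es)
      applied <- TRUE
      break
    }
    if (!applied) break
  }
  invisible(st)
}
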
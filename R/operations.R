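## ---------------------------------------------------------------------------
## Surgery on adjacency sets.  An adjset (see as_adjset) is the minimal
## representation on which the six rearrangement operations act: cut, join,
## double-cut-and-paste, sesqui-cut-and-paste, deletion of a region of
## source-private genes and insertion of a region of target-private genes.
## ---------------------------------------------------------------------------

adj_has <- function(x, key) key %in% x$adj

free_extremities <- function(x) {
  all_ext <- c(paste0(x$genes, ":1", recycle0 = TRUE),
               paste0(x$genes, ":2", recycle0 = TRUE))
  used <- unlist(split_adj(x$adj), use.names = FALSE)
  setdiff(all_ext, used)
}

op_cut <- function(x, adj) {
  stopifnot(adj %in% x$adj)
  x$adj <- setdiff(x$adj, adj)
  x
}

op_join <- function(x, e1, e2) {
  x$adj <- sort(c(x$adj, adj_key(e1, e2)))
  x
}

## cut {p,q} and {r,s}; rejoin as {p,r},{q,s} (pairing 1) or {p,s},{q,r} (2)
op_dcj <- function(x, adj1, adj2, pairing = 1L) {
  p1 <- split_adj(adj1)[[1]]; p2 <- split_adj(adj2)[[1]]
  x$adj <- setdiff(x$adj, c(adj1, adj2))
  new <- if (pairing == 1L) c(adj_key(p1[1], p2[1]), adj_key(p1[2], p2[2]))
         else               c(adj_key(p1[1], p2[2]), adj_key(p1[2], p2[1]))
  x$adj <- sort(c(x$adj, new))
  x
}

## cut {p,q}, join keep_end (one of p, q) to the free extremity free_e
op_sesqui <- function(x, adj, keep_end, free_e) {
  x$adj <- setdiff(x$adj, adj)
  x$adj <- sort(c(x$adj, adj_key(keep_end, free_e)))
  x
}

## delete a contiguous region of genes; flanking extremities (if two) rejoin
op_delete_region <- function(x, ids) {
  ext <- c(paste0(ids, ":1", recycle0 = TRUE), paste0(ids, ":2", recycle0 = TRUE))
  pairs <- split_adj(x$adj)
  touch <- vapply(pairs, function(p) any(p %in% ext), TRUE)
  boundary <- character(0)
  for (p in pairs[touch]) {
    out <- p[!p %in% ext]
    boundary <- c(boundary, out)
  }
  x$adj <- x$adj[!touch]
  x$genes <- setdiff(x$genes, ids)
  if (length(boundary) == 2L) x$adj <- sort(c(x$adj, adj_key(boundary[1], boundary[2])))
  x
}

## insert an ordered signed region; `at` is NULL (new linear chromosome),
## "@" (new circular chromosome), an adjacency key (splice inside) or a free
## extremity (append at a path end)
op_insert_region <- function(x, ids, signs, at = NULL) {
  stopifnot(!any(ids %in% x$genes))
  n <- length(ids)
  x$genes <- sort(c(x$genes, ids))
  internal <- if (n > 1L) adj_key(ext_head(ids, signs)[-n], ext_tail(ids, signs)[-1])
              else character(0)
  first_e <- ext_tail(ids[1], signs[1])
  last_e <- ext_head(ids[n], signs[n])
  if (is.null(at)) {
    x$adj <- sort(c(x$adj, internal))
  } else if (identical(at, "@")) {
    x$adj <- sort(c(x$adj, internal, adj_key(last_e, first_e)))
  } else if (grepl("~", at, fixed = TRUE)) {
    p <- split_adj(at)[[1]]
    x$adj <- setdiff(x$adj, at)
    x$adj <- sort(c(x$adj, internal, adj_key(p[1], first_e), adj_key(last_e, p[2])))
  } else {
    x$adj <- sort(c(x$adj, internal, adj_key(at, first_e)))
  }
  x
}

## --- region bookkeeping ----------------------------------------------------

## maximal contiguous runs (in x) of genes absent from `other_genes`;
## returns a list of ordered id vectors (orientation as walked)
special_runs <- function(x, other_genes) {
  s <- adjset_to_structure(x)
  fam_of <- function(ids) ids
  runs <- list()
  for (ch in s$chrs) {
    sp <- !(ch$id %in% other_genes)
    if (!any(sp)) next
    n <- length(sp)
    if (all(sp)) { runs[[length(runs) + 1L]] <- ch$id; next }
    r <- rle(sp)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    seg <- which(r$values)
    segs <- lapply(seg, function(k) seq(idx_start[k], idx_end[k]))
    if (ch$circular && length(seg) > 1L && r$values[1] && r$values[length(r$values)]) {
      ## wrap-around: first and last runs are one region
      first <- segs[[1]]; last <- segs[[length(segs)]]
      segs[[1]] <- c(last, first)
      segs[[length(segs)]] <- NULL
    }
    for (ix in segs) runs[[length(runs) + 1L]] <- ch$id[ix]
  }
  runs
}

## is this adjacency internal to a run of source-private genes?
adj_within_special <- function(adj, special) {
  p <- split_adj(adj)[[1]]
  all(ext_gene(p) %in% special)
}

## circular chromosomes made entirely of source-private genes
count_special_circles <- function(x, special) {
  s <- adjset_to_structure(x)
  sum(vapply(s$chrs, function(ch) ch$circular && all(ch$id %in% special), TRUE))
}

## --- move enumeration (relative to a fixed target) -------------------------

## All single operations legal on state x when transforming towards target
## `b`.  Excludes the "unnatural" variants: cutting inside a region of
## source-private genes, inserting target-private genes into such a region,
## and standard operations that excise a source-private region into a new
## circle.  Moves are plain data applied by apply_move() (no closures, so
## the byte compiler is not re-triggered per move).
enumerate_moves <- function(x, b, w, insert_cap = 4L) {
  special_a <- setdiff(x$genes, b$genes)
  special_b <- setdiff(b$genes, x$genes)
  moves <- list()
  add <- function(kind, ...) {
    moves[[length(moves) + 1L]] <<- list(kind = kind, ...)
  }
  cuttable <- x$adj[!vapply(x$adj, adj_within_special, TRUE, special = special_a)]
  frees <- free_extremities(x)

  for (adj in cuttable) add("cut", adj = adj)
  if (length(frees) > 1L) {
    cmb <- utils::combn(frees, 2L)
    for (k in seq_len(ncol(cmb))) add("join", e1 = cmb[1, k], e2 = cmb[2, k])
  }
  if (length(cuttable) > 1L) {
    cmb <- utils::combn(cuttable, 2L)
    for (k in seq_len(ncol(cmb))) for (pr in 1:2)
      add("double", a1 = cmb[1, k], a2 = cmb[2, k], pairing = pr)
  }
  for (adj in cuttable) {
    p <- split_adj(adj)[[1]]
    for (keep in p) for (fe in frees)
      add("sesqui", adj = adj, keep = keep, free = fe)
  }
  if (length(special_a))
    for (run in special_runs(x, b$genes))
      add("del_a", run = run)
  if (length(special_b) && length(special_b) <= insert_cap) {
    regions <- signed_orderings(special_b)
    sites <- c(list(NULL, "@"), as.list(cuttable), as.list(frees))
    for (reg in regions) for (at in sites)
      add("ins_b", ids = reg$id, signs = reg$sign, at = at)
  }
  attr(moves, "special_a") <- special_a
  moves
}

## apply one move; NULL when the forbidden circularization guard fires
apply_move <- function(x, mv, special_a) {
  y <- switch(mv$kind,
    cut = op_cut(x, mv$adj),
    join = op_join(x, mv$e1, mv$e2),
    double = op_dcj(x, mv$a1, mv$a2, mv$pairing),
    sesqui = op_sesqui(x, mv$adj, mv$keep, mv$free),
    del_a = op_delete_region(x, mv$run),
    ins_b = op_insert_region(x, mv$ids, mv$signs, mv$at))
  if (length(special_a) && mv$kind %in% c("join", "double", "sesqui")) {
    added <- setdiff(y$adj, x$adj)
    for (ad in added)
      if (adj_closes_special_circle(y, ad, special_a)) return(NULL)
  }
  y
}

## does the chromosome through this adjacency form a circle made entirely of
## source-private genes?
adj_closes_special_circle <- function(y, ad, special_a) {
  p <- split_adj(ad)[[1]]
  if (!all(ext_gene(p) %in% special_a)) return(FALSE)
  nbr <- new.env(parent = emptyenv())
  for (q in split_adj(y$adj)) { nbr[[q[1]]] <- q[2]; nbr[[q[2]]] <- q[1] }
  start <- p[1]
  e <- p[2]
  seen <- character(0)
  repeat {
    g <- ext_gene(e)
    if (!g %in% special_a) return(FALSE)
    e2 <- ext_other(e)
    nxt <- nbr[[e2]]
    if (is.null(nxt)) return(FALSE)       # reached a telomere: a path
    if (nxt == start || nxt %in% seen) return(TRUE)
    seen <- c(seen, e, e2)
    e <- nxt
  }
}

.signed_orderings_cache <- new.env(parent = emptyenv())

## all ordered signed sequences over non-empty subsets of ids (memoized)
signed_orderings <- function(ids) {
  key <- paste(sort(ids), collapse = ",")
  if (!is.null(v <- .signed_orderings_cache[[key]])) return(v)
  out <- list()
  subsets <- unlist(lapply(seq_along(ids), function(k)
    utils::combn(ids, k, simplify = FALSE)), recursive = FALSE)
  for (ss in subsets) {
    perms <- permutations_of(ss)
    for (pp in perms) {
      n <- length(pp)
      for (mask in 0:(2^n - 1)) {
        sg <- ifelse(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0, -1L, 1L)
        out[[length(out) + 1L]] <- list(id = pp, sign = sg)
      }
    }
  }
  .signed_orderings_cache[[key]] <- out
  out
}

permutations_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in permutations_of(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}
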
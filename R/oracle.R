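## ---------------------------------------------------------------------------
## Brute-force reference implementations.  These derive legal moves directly
## from structures (enumerate_moves) and search the operation space; they are
## deliberately independent of the common-graph algorithm they validate.
## ---------------------------------------------------------------------------

## minimal binary heap keyed by numeric priority, integer payloads
heap_new <- function() new.env(parent = emptyenv())
heap_init <- function(h) { h$pr <- numeric(0); h$id <- integer(0); h }
heap_push <- function(h, pr, id) {
  n <- length(h$pr) + 1L
  h$pr[n] <- pr; h$id[n] <- id
  while (n > 1L) {
    p <- n %/% 2L
    if (h$pr[p] <= h$pr[n]) break
    tp <- h$pr[p]; h$pr[p] <- h$pr[n]; h$pr[n] <- tp
    ti <- h$id[p]; h$id[p] <- h$id[n]; h$id[n] <- ti
    n <- p
  }
}
heap_pop <- function(h) {
  n <- length(h$pr)
  if (n == 0L) return(NULL)
  top <- list(pr = h$pr[1], id = h$id[1])
  h$pr[1] <- h$pr[n]; h$id[1] <- h$id[n]
  h$pr <- h$pr[-n]; h$id <- h$id[-n]
  n <- n - 1L; i <- 1L
  while (TRUE) {
    l <- 2L * i; r <- l + 1L; s <- i
    if (l <= n && h$pr[l] < h$pr[s]) s <- l
    if (r <= n && h$pr[r] < h$pr[s]) s <- r
    if (s == i) break
    tp <- h$pr[s]; h$pr[s] <- h$pr[i]; h$pr[i] <- tp
    ti <- h$id[s]; h$id[s] <- h$id[i]; h$id[i] <- ti
    i <- s
  }
  top
}

#' Uniform-cost search for the optimal operation sequence (oracle)
#'
#' Explores all legal single operations (with the model's forbidden variants
#' excluded) from canonical state to canonical state and returns a
#' minimum-cost sequence transforming `a` into `b`.  Intended for small
#' instances (up to roughly six gene occurrences in total).
#'
#' @param a,b `chrom_structure` objects or adjsets.
#' @param w a [weight_scheme()].
#' @param max_weight prune states whose accumulated weight exceeds this.
#' @param mode `"weight"` minimizes total weight; `"length_then_weight"`
#'   minimizes the number of operations first and total weight among
#'   minimum-length sequences (the optimality notion of the exactness
#'   condition for equal gene content under a weight pattern).
#' @return list with `weight`, `length`, `kinds` (operation kinds in order)
#'   and `found`; `found = FALSE` when the bound was exceeded.
#' @export
bfs_shortest_sequence <- function(a, b, w, max_weight = Inf,
                                  mode = c("weight", "length_then_weight")) {
  mode <- match.arg(mode)
  xa <- if (inherits(a, "chrom_structure")) as_adjset(a) else a
  xb <- if (inherits(b, "chrom_structure")) as_adjset(b) else b
  P <- if (mode == "length_then_weight") 1024 else 0
  goal <- adjset_key(xb)
  minw <- min(w$w)
  ## memo: adjacency key -> the two member genes
  agc <- new.env(parent = emptyenv())
  adj_genes <- function(ad) {
    if (!is.null(v <- agc[[ad]])) return(v)
    v <- ext_gene(split_adj(ad)[[1]])
    agc[[ad]] <- v
    v
  }
  ## admissible lower bound on the remaining cost (A*)
  hfun <- function(x) {
    common <- intersect(x$genes, xb$genes)
    M <- length(xb$genes) - length(common)    # still to insert
    E <- length(x$genes) - length(common)     # still to delete
    wrong <- setdiff(x$adj, xb$adj)
    cc <- 0L
    for (ad in wrong) if (all(adj_genes(ad) %in% common)) cc <- cc + 1L
    miss <- length(xb$adj) - (length(x$adj) - length(wrong))
    h_ops <- max(ceiling(cc / 2),
                 if (M > 0) 1L else ceiling(miss / 2),
                 if (E > 0) 1L else 0L)
    h_w <- max(ceiling(cc / 2) * minw,
               if (M > 0) w$w[["ins_b"]] else ceiling(miss / 2) * minw,
               if (E > 0) w$w[["del_a"]] else 0)
    if (mode == "length_then_weight") h_ops * P else h_w
  }
  states <- list(xa)
  keys <- new.env(parent = emptyenv()); assign(adjset_key(xa), 1L, envir = keys)
  dist <- 0; wgt <- 0; len <- 0L
  parent <- 0L; pkind <- NA_character_
  done <- logical(1)
  h <- heap_init(heap_new())
  heap_push(h, hfun(xa), 1L)
  while (!is.null(top <- heap_pop(h))) {
    i <- top$id
    if (done[i]) next
    done[i] <- TRUE
    ki <- adjset_key(states[[i]])
    if (ki == goal) {
      kinds <- character(0); j <- i
      while (parent[j] != 0L) { kinds <- c(pkind[j], kinds); j <- parent[j] }
      return(list(weight = wgt[i], length = len[i], kinds = kinds, found = TRUE))
    }
    mvs <- enumerate_moves(states[[i]], xb, w)
    spa <- attr(mvs, "special_a")
    for (mv in mvs) {
      y <- apply_move(states[[i]], mv, spa)
      if (is.null(y)) next
      wk <- op_weight(w, mv$kind)
      nw <- wgt[i] + wk
      if (nw > max_weight + 1e-9) next
      hy <- hfun(y)
      if (mode == "weight" && nw + hy > max_weight + 1e-9) next
      nd <- dist[i] + P + wk
      ky <- adjset_key(y)
      j <- if (exists(ky, envir = keys, inherits = FALSE)) get(ky, envir = keys) else NA_integer_
      if (is.na(j)) {
        j <- length(states) + 1L
        states[[j]] <- y
        assign(ky, j, envir = keys)
        dist[j] <- Inf; done[j] <- FALSE
        parent[j] <- 0L; pkind[j] <- NA_character_; wgt[j] <- Inf; len[j] <- 0L
      }
      if (nd < dist[j] - 1e-9) {
        dist[j] <- nd; wgt[j] <- nw; len[j] <- len[i] + 1L
        parent[j] <- i; pkind[j] <- mv$kind
        heap_push(h, nd + hy, j)
      }
    }
  }
  list(weight = NA_real_, length = NA_integer_, kinds = NULL, found = FALSE)
}

## Second, independent search: iterative-deepening DFS on the number of
## operations; used to cross-check the uniform-cost oracle under unit weights.
iddfs_min_ops <- function(a, b, w = weight_scheme("none"), max_depth = 8L) {
  xa <- if (inherits(a, "chrom_structure")) as_adjset(a) else a
  xb <- if (inherits(b, "chrom_structure")) as_adjset(b) else b
  goal <- adjset_key(xb)
  for (depth in 0:max_depth) {
    seen <- new.env(parent = emptyenv())
    found <- dls(xa, goal, xb, w, depth, seen)
    if (found) return(depth)
  }
  NA_integer_
}

dls <- function(x, goal, xb, w, depth, seen) {
  k <- adjset_key(x)
  if (k == goal) return(TRUE)
  if (depth == 0L) return(FALSE)
  prev <- if (exists(k, envir = seen, inherits = FALSE)) get(k, envir = seen) else -1L
  if (prev >= depth) return(FALSE)
  assign(k, depth, envir = seen)
  mvs <- enumerate_moves(x, xb, w)
  spa <- attr(mvs, "special_a")
  for (mv in mvs) {
    y <- apply_move(x, mv, spa)
    if (is.null(y)) next
    if (dls(y, goal, xb, w, depth - 1L, seen)) return(TRUE)
  }
  FALSE
}

## --- enumeration of small structures ---------------------------------------

set_partitions <- function(v) {
  if (length(v) == 0L) return(list(list()))
  first <- v[1]; rest <- v[-1]
  out <- list()
  for (p in set_partitions(rest)) {
    for (i in seq_along(p)) {
      q <- p; q[[i]] <- c(first, q[[i]])
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(first))
  }
  out
}

chromosome_variants <- function(ids) {
  out <- list()
  for (ord in permutations_of(ids)) {
    n <- length(ord)
    for (mask in 0:(2^n - 1)) {
      sg <- ifelse(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0, -1L, 1L)
      tok <- ifelse(sg < 0, paste0("-", ord), ord)
      for (circ in c(FALSE, TRUE))
        out[[length(out) + 1L]] <- chromosome(tok, circ)
    }
  }
  out
}

#' Enumerate all chromosome structures over a gene set
#'
#' @param genes character vector of gene ids.
#' @param exact if `TRUE` every gene is used; otherwise all subsets
#'   (including the empty structure) are enumerated.
#' @return list of canonical `chrom_structure` objects, deduplicated.
#' @export
all_structures <- function(genes, exact = TRUE) {
  gene_sets <- if (exact) list(genes) else {
    c(list(character(0)),
      unlist(lapply(seq_along(genes), function(k)
        utils::combn(genes, k, simplify = FALSE)), recursive = FALSE))
  }
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (gs in gene_sets) {
    if (length(gs) == 0L) {
      s <- chrom_structure(list())
      k <- structure_key(s)
      if (!exists(k, envir = seen, inherits = FALSE)) {
        assign(k, TRUE, envir = seen); out[[length(out) + 1L]] <- s
      }
      next
    }
    for (p in set_partitions(gs)) {
      blocks <- lapply(p, chromosome_variants)
      idx <- rep(1L, length(blocks))
      repeat {
        chrs <- lapply(seq_along(blocks), function(i) blocks[[i]][[idx[i]]])
        s <- tryCatch(canonical_structure(chrom_structure(chrs)), error = function(e) NULL)
        if (!is.null(s)) {
          k <- structure_key(s)
          if (!exists(k, envir = seen, inherits = FALSE)) {
            assign(k, TRUE, envir = seen); out[[length(out) + 1L]] <- s
          }
        }
        j <- length(blocks)
        while (j > 0L) {
          idx[j] <- idx[j] + 1L
          if (idx[j] <= length(blocks[[j]])) break
          idx[j] <- 1L; j <- j - 1L
        }
        if (j == 0L) break
      }
    }
  }
  out
}

## --- exhaustive Steiner tree -----------------------------------------------

#' Brute-force minimum Steiner tree weight over small structure universes
#'
#' Runs the Dreyfus-Wagner dynamic program on the complete graph of all
#' structures over subsets of `universe_genes`, with metric closure applied
#' first.  Guarded against combinatorial explosion.
#'
#' @param terminals list of `chrom_structure` objects (at most 5).
#' @param metric `"breakpoint"` or `"biological"`.
#' @param universe_genes gene ids spanning the candidate ancestors (at most
#'   3 for exhaustive search).
#' @param w weight scheme for the biological metric.
#' @param dmat optional precomputed distance matrix over the universe
#'   (with attribute `"keys"` mapping structures to rows).
#' @return optimal Steiner tree weight (numeric).
#' @export
brute_force_steiner <- function(terminals, metric = c("breakpoint", "biological"),
                                universe_genes, w = NULL, dmat = NULL) {
  metric <- match.arg(metric)
  if (length(terminals) > 5L) stop("brute-force Steiner limited to 5 terminals")
  if (length(universe_genes) > 3L) stop("brute-force Steiner limited to 3-gene universes")
  if (is.null(dmat)) dmat <- universe_distance_matrix(universe_genes, metric, w)
  keys <- attr(dmat, "keys")
  tidx <- vapply(terminals, function(s) {
    k <- structure_key(canonical_structure(s))
    i <- match(k, keys)
    if (is.na(i)) stop("terminal outside the enumerated universe")
    i
  }, 1L)
  tidx <- unique(tidx)
  k <- length(tidx)
  if (k == 1L) return(0)
  nV <- nrow(dmat)
  ## Dreyfus-Wagner over terminal subsets
  nS <- 2^k - 1
  S <- matrix(Inf, nrow = nS, ncol = nV)
  for (i in seq_len(k)) S[2^(i - 1), ] <- dmat[tidx[i], ]
  singles <- 2^(seq_len(k) - 1)
  for (D in seq_len(nS)) {
    if (D %in% singles) next
    ## merge step over proper sub-splits
    sub <- D
    best <- rep(Inf, nV)
    E <- bitwAnd(D, D - 1)  # iterate submasks
    Dsub <- E
    while (Dsub > 0) {
      comp <- bitwAnd(D, bitwNot(Dsub))
      if (comp > 0 && Dsub < comp) { # each split once
        best <- pmin(best, S[Dsub, ] + S[comp, ])
      }
      Dsub <- bitwAnd(Dsub - 1, D)
    }
    ## metric-closure relaxation: one pass suffices on a metric
    S[D, ] <- apply(dmat + rep(best, each = nV), 1, min)
  }
  min(S[nS, ])
}

## cache of enumerated universes and their distance matrices
.genrearr_cache <- new.env(parent = emptyenv())

universe_distance_matrix <- function(universe_genes, metric, w = NULL,
                                     exact = FALSE) {
  tag <- paste(metric, exact, paste(sort(universe_genes), collapse = ","),
               if (!is.null(w)) paste(w$pattern, paste(w$w, collapse = ",")) else "",
               sep = "|")
  if (exists(tag, envir = .genrearr_cache, inherits = FALSE))
    return(get(tag, envir = .genrearr_cache))
  univ <- all_structures(sort(universe_genes), exact = exact)
  n <- length(univ)
  adjs <- lapply(univ, as_adjset)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    d <- if (metric == "breakpoint") breakpoint_distance(adjs[[i]], adjs[[j]])
         else biological_distance(univ[[i]], univ[[j]], w)$symmetric
    D[i, j] <- D[j, i] <- d
  }
  ## metric closure (heuristic distances can violate the triangle inequality)
  for (m in seq_len(n)) D <- pmin(D, outer(D[, m], D[m, ], "+"))
  attr(D, "keys") <- vapply(univ, structure_key, "")
  attr(D, "structures") <- univ
  assign(tag, D, envir = .genrearr_cache)
  D
}
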
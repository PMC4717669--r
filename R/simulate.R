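## ---------------------------------------------------------------------------
## Seeded synthetic data: random chromosome structures and evolution along a
## tree, recording the true ancestral arrangement.
## ---------------------------------------------------------------------------

#' Configuration for the evolution simulator
#'
#' @param op_rates named probabilities over operation kinds
#'   (`double`, `sesqui`, `cut`, `join`, `del`, `ins`); they are normalized.
#'   The default uses standard operations only, so gene content is conserved.
#' @param n_events number of events per edge, or the mean of a Poisson draw
#'   when `poisson = TRUE`.
#' @param poisson draw the per-edge event count from a Poisson distribution.
#' @param n_genes,alphabet gene alphabet for [random_structure()].
#' @param circular_prob probability that a chromosome is circular.
#' @param n_chrom number of chromosomes of a random structure.
#' @param paralog_birth_prob probability that a gene gets a duplicated
#'   paralog in [random_structure()].
#' @return a list of class `evolution_config`.
#' @export
evolution_config <- function(op_rates = c(double = 0.5, sesqui = 0.3,
                                          cut = 0.1, join = 0.1,
                                          del = 0, ins = 0),
                             n_events = 2, poisson = FALSE,
                             n_genes = 5, alphabet = NULL,
                             circular_prob = 0.5, n_chrom = 1,
                             paralog_birth_prob = 0) {
  stopifnot(all(op_rates >= 0), sum(op_rates) > 0,
            circular_prob >= 0, circular_prob <= 1,
            paralog_birth_prob >= 0, paralog_birth_prob <= 1)
  structure(list(op_rates = op_rates / sum(op_rates), n_events = n_events,
                 poisson = poisson, n_genes = n_genes,
                 alphabet = alphabet %||% paste0("g", seq_len(n_genes)),
                 circular_prob = circular_prob, n_chrom = n_chrom,
                 paralog_birth_prob = paralog_birth_prob),
            class = "evolution_config")
}

#' Random chromosome structure
#'
#' @param cfg an [evolution_config()].
#' @return a `chrom_structure`.  Uses the current RNG state; seed with
#'   `set.seed()` for reproducibility.
#' @export
random_structure <- function(cfg = evolution_config()) {
  genes <- cfg$alphabet
  dup <- genes[stats::runif(length(genes)) < cfg$paralog_birth_prob]
  ids <- c(if (length(dup)) paste0(setdiff(genes, dup)),
           if (length(dup)) c(paste0(dup, ".1"), paste0(dup, ".2")))
  if (!length(dup)) ids <- genes
  ids <- sample(ids)
  cuts <- sort(sample(seq_len(max(1L, length(ids) - 1L)),
                      min(cfg$n_chrom - 1L, length(ids) - 1L)))
  bounds <- c(0L, cuts, length(ids))
  chrs <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    seg <- ids[(bounds[k] + 1L):bounds[k + 1L]]
    sgn <- sample(c(1L, -1L), length(seg), replace = TRUE)
    chrs[[k]] <- chromosome(ifelse(sgn < 0, paste0("-", seg), seg),
                            circular = stats::runif(1) < cfg$circular_prob)
  }
  chrom_structure(chrs)
}

## one random operation applied to an adjset (free evolution, no target)
random_op <- function(x, cfg, fresh_counter) {
  kinds <- names(cfg$op_rates)[cfg$op_rates > 0]
  probs <- cfg$op_rates[cfg$op_rates > 0]
  for (try in 1:20) {
    kind <- sample(kinds, 1L, prob = probs)
    frees <- free_extremities(x)
    y <- switch(kind,
      cut = if (length(x$adj)) op_cut(x, sample(x$adj, 1L)) else NULL,
      join = if (length(frees) > 1L) {
        e <- sample(frees, 2L); op_join(x, e[1], e[2])
      } else NULL,
      double = if (length(x$adj) > 1L) {
        e <- sample(x$adj, 2L); op_dcj(x, e[1], e[2], sample(1:2, 1L))
      } else NULL,
      sesqui = if (length(x$adj) >= 1L && length(frees) >= 1L) {
        a1 <- sample(x$adj, 1L)
        p <- split_adj(a1)[[1]]
        op_sesqui(x, a1, sample(p, 1L), sample(frees, 1L))
      } else NULL,
      del = if (length(x$genes) > 1L) {
        op_delete_region(x, sample(x$genes, 1L))
      } else NULL,
      ins = {
        gid <- paste0("n", fresh_counter$i)
        fresh_counter$i <- fresh_counter$i + 1L
        at <- if (length(x$adj)) sample(c(list(NULL), as.list(x$adj)), 1L)[[1]] else NULL
        op_insert_region(x, gid, sample(c(1L, -1L), 1L), at)
      })
    if (!is.null(y)) return(y)
  }
  x
}

#' Simulate evolution along a tree
#'
#' Applies a sampled number of random operations on every edge, starting
#' from the root structure, and records the true structure at every node.
#'
#' @param root a `chrom_structure` for the root.
#' @param tree an `ape` `phylo` object (rooted) or a Newick string.
#' @param cfg an [evolution_config()].
#' @return list with `arrangement` (structures indexed by node number,
#'   leaves first as in `ape`), `tree`, and `leaves` (named list of leaf
#'   structures).
#' @export
simulate_evolution <- function(root, tree, cfg = evolution_config()) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  arrangement <- vector("list", nnode)
  rootid <- ntip + 1L
  arrangement[[rootid]] <- root
  fresh <- new.env(parent = emptyenv()); fresh$i <- 1L
  ## edges in preorder
  eo <- tree$edge[order(tree$edge[, 1]), , drop = FALSE]
  ## traverse from root
  stack <- rootid
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    for (u in kids) {
      x <- as_adjset(arrangement[[v]])
      k <- if (cfg$poisson) stats::rpois(1, cfg$n_events) else cfg$n_events
      if (k > 0) for (t in seq_len(k)) x <- random_op(x, cfg, fresh)
      arrangement[[u]] <- adjset_to_structure(x)
      stack <- c(stack, u)
    }
  }
  leaves <- stats::setNames(arrangement[seq_len(ntip)], tree$tip.label)
  list(arrangement = arrangement, tree = tree, leaves = leaves)
}
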
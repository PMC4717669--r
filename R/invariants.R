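## ---------------------------------------------------------------------------
## Readily calculated properties of the initial common graph that decompose
## the total weight of the emitted scenario:
##   C = B + S + (D - P) + eps (B' + n)
## B  = number of special nodes (every special node leaves the graph through
##      exactly one operation that decrements the special-node count: a
##      deletion or a merge);
## S  = step-2 operation count from the maximal conventional-edge regions;
## D-P = extra operations that do not decrement the special-node count,
##      outside step 2 (D is the per-component extra cost of individual
##      processing and P the operations saved by the step-3 combinations);
## eps = b-region insertion weight minus 1; B' = initial circles with a
##      b-node and no a-node; n = b-node deletions beyond B' (at most 2).
## B, S, B' are computed directly from the initial graph; the scenario is
## decomposed per category and the identities are what the test suite
## asserts.  With the five standard weights equal to 1 the formula value C
## equals the scenario's total weight.
## ---------------------------------------------------------------------------

graph_B <- function(g) sum(g$kind == "spec")

## step-2 operation count: for each maximal region of conventional edges,
## floor(length/2), plus 1 for an odd region touching a path end, minus 1
## for a region forming a whole circle
graph_S <- function(g) {
  S <- 0L
  for (comp in cg_components(g)) {
    if (!comp$shape %in% c("path", "circle")) next
    ne <- length(comp$edges)
    conv <- vapply(comp$edges, function(i) cg_is_conv_edge(g, i), TRUE)
    if (!any(conv)) next
    if (comp$shape == "circle" && all(conv)) {
      S <- S + ne %/% 2L - 1L
      next
    }
    idx <- seq_len(ne)
    if (comp$shape == "circle") {
      k <- which(!conv)[1]
      rot <- c(seq_len(ne)[-seq_len(k)], seq_len(k))
      idx <- idx[rot]; conv <- conv[rot]
    }
    r <- rle(conv)
    hi <- cumsum(r$lengths); lo <- hi - r$lengths + 1L
    for (ri in which(r$values)) {
      l <- r$lengths[ri]
      S <- S + l %/% 2L
      boundary <- comp$shape == "path" && (idx[lo[ri]] == 1L || idx[hi[ri]] == ne)
      if (boundary && l %% 2L == 1L) S <- S + 1L
    }
  }
  S
}

graph_Bprime <- function(g) {
  n <- 0L
  for (comp in cg_components(g)) {
    if (comp$shape != "circle") next
    sides <- g$side[comp$order[g$kind[comp$order] == "spec"]]
    if (length(sides) && any(sides == "b") && !any(sides == "a")) n <- n + 1L
  }
  n
}

#' Invariants of the initial common graph and the weight-formula decomposition
#'
#' Computes B (special nodes), S (step-2 operations from the conventional-
#' edge regions), B' (circles with b-nodes only) and eps directly from the
#' initial common graph, then runs the transformation once in bookkeeping
#' mode and decomposes its scenario: operations that decrement the number of
#' special nodes (predicted by B), step-2 operations (predicted by S), extra
#' operations (`extra` = D - P), b-node deletions (predicted by B' + n with
#' n between 0 and 2), and the predicted total
#' `C = B + S + (D - P) + eps * (B' + n)`, which equals the scenario weight
#' when the five standard-operation weights are 1.
#'
#' @param a,b `chrom_structure` objects.
#' @param w a [weight_scheme()].
#' @return list with fields `B`, `S`, `B_prime`, `eps`, `extra`, `P`, `n`,
#'   `n_ops`, `ops_spec_decreasing`, `ops_step2`, `ops_bdel`, `C`,
#'   `total_weight`.
#' @export
compute_invariants <- function(a, b, w = weight_scheme("none")) {
  g <- build_common_graph(a, b)
  B <- graph_B(g)
  S <- graph_S(g)
  Bp <- graph_Bprime(g)
  eps <- op_weight(w, "ins_b") - 1
  st <- eng_new(a, b, w)
  step1(st); step2(st)
  nlog2 <- length(st$log)
  step3(st)
  P <- (length(st$log) - nlog2) + length(st$pending)
  step4(st); step5(st)
  dspec <- vapply(st$log, `[[`, 0L, "dspec")
  phase <- vapply(st$log, `[[`, "", "phase")
  fwd <- vapply(st$log, `[[`, "", "fwd")
  wts <- vapply(st$log, `[[`, 0, "weight")
  ops_dec <- sum(dspec > 0L)
  ops_s2 <- sum(phase == "s2")
  nbdel <- sum(fwd == "ins_b")
  extra <- length(st$log) - ops_dec - ops_s2
  nsmall <- nbdel - Bp
  list(B = B, S = S, B_prime = Bp, eps = eps, extra = extra, P = P,
       n = nsmall, n_ops = length(st$log),
       ops_spec_decreasing = ops_dec, ops_step2 = ops_s2, ops_bdel = nbdel,
       C = B + S + extra + eps * (Bp + nsmall),
       total_weight = sum(wts))
}
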
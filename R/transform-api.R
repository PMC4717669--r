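## ---------------------------------------------------------------------------
## Public entry point of the distance algorithm and scenario assembly.
## ---------------------------------------------------------------------------

#' Minimum-weight transformation of one chromosome structure into another
#'
#' Builds the common graph of `a` and `b` and runs the five-step
#' transformation into final form, mirroring every graph operation onto the
#' structures.  Operations applied on the b side of the graph are inverted
#' and appended in reverse so that the returned scenario transforms `a` into
#' `b` when replayed forwards.
#'
#' The result is exact for minimum-length sequences when the two structures
#' have equal gene content and the weights follow the circular or linear
#' pattern, and within one deletion weight of the optimum when the five
#' standard-operation weights are equal to some d and the b-region insertion
#' weight c satisfies d <= c <= 2d; otherwise it is a heuristic.
#'
#' @param a,b `chrom_structure` objects with unique gene ids.
#' @param w a [weight_scheme()].
#' @return a `rearrangement_scenario`: list with `ops` (operation records),
#'   `total_weight`, `length`, `source`, `target`.
#' @export
transform_to_final <- function(a, b, w = weight_scheme("none")) {
  viol <- validate_weights(w)
  if (length(viol) && any(grepl("non-positive", viol)))
    stop(paste(viol, collapse = "; "))
  st <- eng_new(a, b, w)
  step1(st)
  step2(st)
  step3(st)
  step4(st)
  step5(st)
  ## sanity: graph is final, evolving structures have met
  for (e in engine_components(st))
    stop("internal: non-final component of type ", e$type, " remains")
  if (adjset_key(st$sa) != adjset_key(st$sb))
    stop("internal: transformation did not reach the target structure")
  assemble_scenario(st, a, b)
}

assemble_scenario <- function(st, a, b) {
  fwd <- Filter(function(x) x$side == "a", st$log)
  bwd <- Filter(function(x) x$side == "b", st$log)
  ops <- c(fwd, lapply(rev(bwd), function(x) {
    list(side = "a", fwd = x$fwd, weight = x$weight,
         removed = x$added, added = x$removed,
         genes = character(0), genes_added = x$genes, tokens = x$tokens)
  }))
  cur <- as_adjset(a)
  records <- vector("list", length(ops))
  kind_map <- c(double = "DOUBLE", sesqui = "SESQUI", cut = "CUTJOIN",
                join = "CUTJOIN", del_a = "DELETE_REGION", ins_b = "INSERT_REGION")
  for (k in seq_along(ops)) {
    o <- ops[[k]]
    stopifnot(all(o$removed %in% cur$adj))
    cur$adj <- sort(c(setdiff(cur$adj, o$removed), o$added))
    if (length(o$genes)) cur$genes <- setdiff(cur$genes, o$genes)
    ga <- o$genes_added %||% character(0)
    if (length(ga)) cur$genes <- sort(c(cur$genes, ga))
    records[[k]] <- list(kind = unname(kind_map[o$fwd]), op = o$fwd,
                         weight = o$weight, removed = o$removed,
                         added = o$added, genes_deleted = o$genes,
                         genes_inserted = ga, region = o$tokens,
                         after = cur)
  }
  if (adjset_key(cur) != adjset_key(as_adjset(b)))
    stop("internal: scenario replay does not reproduce the target")
  structure(list(ops = records,
                 total_weight = sum(vapply(records, `[[`, 0, "weight")),
                 length = length(records),
                 source = a$name, target = b$name),
            class = "rearrangement_scenario")
}

#' @export
print.rearrangement_scenario <- function(x, ...) {
  cat(sprintf("rearrangement scenario %s -> %s: %d operation(s), total weight %.4g\n",
              if (nzchar(x$source)) x$source else "a",
              if (nzchar(x$target)) x$target else "b",
              x$length, x$total_weight))
  for (o in x$ops) {
    extra <- if (length(o$genes_deleted)) paste(" -", paste(o$genes_deleted, collapse = " "))
             else if (length(o$genes_inserted)) paste(" +", paste(o$genes_inserted, collapse = " "))
             else ""
    cat(sprintf("  %-14s w=%.3g%s\n", o$kind, o$weight, extra))
  }
  invisible(x)
}

#' Replay a scenario on a structure
#'
#' @param scen a `rearrangement_scenario`.
#' @param a the source `chrom_structure`.
#' @return the resulting `chrom_structure`.
#' @export
replay_scenario <- function(scen, a) {
  cur <- as_adjset(a)
  for (o in scen$ops) {
    stopifnot(all(o$removed %in% cur$adj))
    cur$adj <- sort(c(setdiff(cur$adj, o$removed), o$added))
    if (length(o$genes_deleted)) cur$genes <- setdiff(cur$genes, o$genes_deleted)
    if (length(o$genes_inserted)) cur$genes <- sort(c(cur$genes, o$genes_inserted))
  }
  adjset_to_structure(cur)
}
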
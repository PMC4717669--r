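## ---------------------------------------------------------------------------
## Distances between chromosome structures.
## ---------------------------------------------------------------------------

#' Breakpoint distance
#'
#' The number of extremity pairs glued in one structure but not in the other
#' plus the number of genes present in exactly one structure.  Symmetric by
#' construction.  Paralogs must be resolved (unique ids) beforehand.
#'
#' @param a,b `chrom_structure` objects or adjsets.
#' @return non-negative integer.
#' @export
breakpoint_distance <- function(a, b) {
  xa <- if (inherits(a, "chrom_structure")) as_adjset(a) else a
  xb <- if (inherits(b, "chrom_structure")) as_adjset(b) else b
  adj_sym <- length(setdiff(xa$adj, xb$adj)) + length(setdiff(xb$adj, xa$adj))
  gene_sym <- length(setdiff(xa$genes, xb$genes)) + length(setdiff(xb$genes, xa$genes))
  adj_sym + gene_sym
}

#' Biological distance between two structures
#'
#' Runs the common-graph transformation in both directions and reports the
#' one-way weights, their mean (the symmetric biological distance) and the
#' exactness class of the weight scheme on this pair.
#'
#' @param a,b `chrom_structure` objects.
#' @param w a [weight_scheme()].
#' @return a `distance_report` with fields `one_way_ab`, `one_way_ba`,
#'   `symmetric`, `exactness_class`.
#' @export
biological_distance <- function(a, b, w = weight_scheme("none")) {
  sab <- transform_to_final(a, b, w)
  sba <- transform_to_final(b, a, w)
  eq <- setequal(structure_genes(a), structure_genes(b))
  structure(list(one_way_ab = sab$total_weight, one_way_ba = sba$total_weight,
                 symmetric = (sab$total_weight + sba$total_weight) / 2,
                 exactness_class = exactness_class(w, equal_content = eq)),
            class = "distance_report")
}

#' @export
print.distance_report <- function(x, ...) {
  cat(sprintf("biological distance: %.4g (a->b %.4g, b->a %.4g) [%s]\n",
              x$symmetric, x$one_way_ab, x$one_way_ba, x$exactness_class))
  invisible(x)
}
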
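## ---------------------------------------------------------------------------
## Structure-pair generators used for validation: an exhaustive enumeration
## of all small pairs up to gene relabelling, and seeded random pairs with a
## prescribed total number of gene occurrences.
## ---------------------------------------------------------------------------

## canonical key of a pair up to renaming of shared / a-private / b-private
## genes within their classes
pair_isomorphism_key <- function(a, b) {
  ga <- structure_genes(a); gb <- structure_genes(b)
  common <- sort(intersect(ga, gb))
  aonly <- sort(setdiff(ga, gb)); bonly <- sort(setdiff(gb, ga))
  best <- NULL
  for (pc in permutations_of(common)) for (pa in permutations_of(aonly))
    for (pb in permutations_of(bonly)) {
      map <- c(stats::setNames(paste0("c", seq_along(pc)), pc),
               stats::setNames(paste0("x", seq_along(pa)), pa),
               stats::setNames(paste0("y", seq_along(pb)), pb))
      rl <- function(s) {
        s$chrs <- lapply(s$chrs, function(ch) { ch$id <- unname(map[ch$id]); ch })
        s
      }
      key <- paste(write_structure(rl(a), "grimm"),
                   write_structure(rl(b), "grimm"), sep = "#")
      if (is.null(best) || key < best) best <- key
    }
  best
}

#' Enumerate all small structure pairs up to gene relabelling
#'
#' Every pair of structures with at most `max_occ` gene occurrences in
#' total, over every split into shared and private gene content, one
#' representative per relabelling-isomorphism class.  Distances are
#' invariant under renaming, so sweeps over these representatives are
#' exhaustive in substance.
#'
#' @param max_occ maximum total number of gene occurrences (both structures).
#' @return list of `list(a, b)` pairs.
#' @export
enumerate_structure_pairs <- function(max_occ = 4L) {
  key <- paste0("pairs", max_occ)
  if (!is.null(v <- .genrearr_cache[[key]])) return(v)
  univ_genes <- paste0("g", seq_len(max_occ))
  seen <- new.env(parent = emptyenv())
  pairs <- list()
  for (na in 0:(max_occ - 1L)) for (nb in 0:(max_occ - na)) {
    if (na + nb == 0L) next
    ga <- univ_genes[seq_len(na)]
    for (nc in 0:min(na, nb)) {
      gb <- c(ga[seq_len(nc)],
              if (nb - nc > 0) paste0("h", seq_len(nb - nc)) else character(0))
      for (sa in all_structures(ga, exact = TRUE))
        for (sb in all_structures(gb, exact = TRUE)) {
          k <- pair_isomorphism_key(sa, sb)
          if (!exists(k, envir = seen, inherits = FALSE)) {
            assign(k, TRUE, envir = seen)
            pairs[[length(pairs) + 1L]] <- list(a = sa, b = sb)
          }
        }
    }
  }
  .genrearr_cache[[key]] <- pairs
  pairs
}

#' Seeded random structure pair with a given total size
#'
#' Draws a pair of structures sharing some gene families, with `total_occ`
#' gene occurrences in total across both, random signs, one or two
#' chromosomes per structure and random topologies.  Uses the current RNG
#' state.
#'
#' @param total_occ total number of gene occurrences.
#' @param circular_only restrict to circular chromosomes.
#' @param paralogs if `TRUE`, shared families may carry up to
#'   `max_paralogs` copies per side.
#' @param max_paralogs cap on paralogs per family and side.
#' @return `list(a, b)`.
#' @export
random_structure_pair <- function(total_occ = 6L, circular_only = FALSE,
                                  paralogs = FALSE, max_paralogs = 3L) {
  if (!paralogs) {
    ncom <- sample(seq_len(max(1L, total_occ %/% 2L)), 1L)
    rest <- total_occ - 2L * ncom
    na <- if (rest > 0) sample(0:rest, 1L) else 0L
    nb <- rest - na
    ids_a <- c(paste0("g", seq_len(ncom)),
               if (na) paste0("x", seq_len(na)) else character(0))
    ids_b <- c(paste0("g", seq_len(ncom)),
               if (nb) paste0("y", seq_len(nb)) else character(0))
  } else {
    ## distribute occurrences over 1-2 families with small paralog counts
    nfam <- sample(1:2, 1L)
    ids_a <- character(0); ids_b <- character(0)
    remaining <- total_occ
    for (k in seq_len(nfam)) {
      ca <- sample(seq_len(min(max_paralogs, max(1L, remaining %/% 2L))), 1L)
      cb <- sample(seq_len(min(max_paralogs, max(1L, remaining - ca))), 1L)
      ids_a <- c(ids_a, paste0("g", k, ".", seq_len(ca)))
      ids_b <- c(ids_b, paste0("g", k, ".", seq_len(cb)))
      remaining <- remaining - ca - cb
      if (remaining <= 0) break
    }
  }
  mk <- function(ids) {
    ids <- sample(ids)
    n <- length(ids)
    sgn <- sample(c(1L, -1L), n, replace = TRUE)
    k <- if (n > 1L) sample(1:2, 1L) else 1L
    cuts <- if (k > 1L) sort(sample(seq_len(n - 1L), k - 1L)) else integer(0)
    bounds <- c(0L, cuts, n)
    chrs <- list()
    for (q in seq_len(length(bounds) - 1L)) {
      seg <- (bounds[q] + 1L):bounds[q + 1L]
      chrs[[q]] <- chromosome(
        ifelse(sgn[seg] < 0, paste0("-", ids[seg]), ids[seg]),
        circular = circular_only || stats::runif(1) < 0.5)
    }
    chrom_structure(chrs)
  }
  list(a = mk(ids_a), b = mk(ids_b))
}
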
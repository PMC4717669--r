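## ---------------------------------------------------------------------------
## Chromosome structures: sets of linear/circular chromosomes whose elements
## are signed, possibly paralog-indexed genes.  Internally a chromosome is
## list(id = character, sign = integer, circular = logical) where id is
## "family" or "family.j" for paralog j; a structure is a list of chromosomes
## plus a name.  Gene ids must be unique within a structure.
## ---------------------------------------------------------------------------

#' Create a chromosome
#'
#' @param tokens character vector of signed gene tokens, e.g. `c("cox1", "-ls3")`.
#'   A leading `-` marks the reverse strand.
#' @param circular logical, `TRUE` for a circular chromosome.
#' @return a `chromosome` object.
#' @export
chromosome <- function(tokens, circular = FALSE) {
  if (length(tokens) == 0L) stop("chromosome must contain at least one gene")
  sign <- ifelse(startsWith(tokens, "-"), -1L, 1L)
  id <- sub("^-", "", tokens)
  if (any(!nzchar(id))) stop("empty gene token")
  structure(list(id = id, sign = sign, circular = isTRUE(circular)),
            class = "chromosome")
}

#' Create a chromosome structure
#'
#' @param chrs list of [chromosome()] objects.
#' @param name optional name.
#' @return a `chrom_structure` object.
#' @export
chrom_structure <- function(chrs = list(), name = "") {
  ids <- unlist(lapply(chrs, `[[`, "id"))
  if (anyDuplicated(ids))
    stop("duplicate gene id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         " (index paralogs as family.j, or resolve via paralog matching)")
  structure(list(chrs = chrs, name = name), class = "chrom_structure")
}

gene_family <- function(id) sub("\\.[0-9]+$", "", id)
gene_paralog <- function(id) {
  m <- regmatches(id, regexpr("\\.[0-9]+$", id))
  ifelse(lengths(regmatches(id, gregexpr("\\.[0-9]+$", id))) > 0,
         as.integer(sub("^\\.", "", m)), NA_integer_)
}

#' @export
print.chrom_structure <- function(x, ...) {
  cat("chromosome structure", if (nzchar(x$name)) sQuote(x$name) else "",
      "with", length(x$chrs), "chromosome(s)\n")
  for (ch in x$chrs) {
    tok <- ifelse(ch$sign < 0, paste0("-", ch$id), ch$id)
    cat(" ", paste(tok, collapse = " "),
        if (ch$circular) "@" else "$", "\n")
  }
  invisible(x)
}

#' @export
format.chrom_structure <- function(x, ...) write_structure(x, dialect = "grimm")

## --- canonical forms -------------------------------------------------------

signed_tokens <- function(ch) ifelse(ch$sign < 0, paste0("-", ch$id), ch$id)

rev_comp_tokens <- function(tok) {
  rev(ifelse(startsWith(tok, "-"), sub("^-", "", tok), paste0("-", tok)))
}

canonical_tokens <- function(ch) {
  tok <- signed_tokens(ch)
  if (!ch$circular) {
    alt <- rev_comp_tokens(tok)
    if (paste(alt, collapse = " ") < paste(tok, collapse = " ")) alt else tok
  } else {
    n <- length(tok)
    best <- NULL
    for (cand in list(tok, rev_comp_tokens(tok))) {
      for (r in seq_len(n)) {
        rot <- cand[c(seq(r, n), if (r > 1) seq_len(r - 1))]
        key <- paste(rot, collapse = " ")
        if (is.null(best) || key < best$key) best <- list(key = key, tok = rot)
      }
    }
    best$tok
  }
}

#' Canonicalize a structure
#'
#' Rewrites every chromosome in its lexicographically least reading (over
#' rotations of both strand readings for circles, over the two readings for
#' linear chromosomes) and sorts chromosomes, so equal structures have
#' identical canonical forms.
#'
#' @param s a `chrom_structure`.
#' @return the canonicalized `chrom_structure`.
#' @export
canonical_structure <- function(s) {
  chrs <- lapply(s$chrs, function(ch) chromosome(canonical_tokens(ch), ch$circular))
  keys <- vapply(chrs, function(ch)
    paste0(if (ch$circular) "@" else "$", paste(signed_tokens(ch), collapse = " ")),
    "")
  s$chrs <- chrs[order(keys)]
  s
}

#' Test equality of two structures
#'
#' Equality is invariant under rotation of circular chromosomes, full reversal
#' with orientation flip of any chromosome, and chromosome order.
#'
#' @param a,b `chrom_structure` objects.
#' @return logical.
#' @export
structures_equal <- function(a, b) structure_key(a) == structure_key(b)

#' @rdname structures_equal
#' @export
structure_key <- function(a) {
  ad <- structure_adjacencies(a)
  paste(paste(sort(structure_genes(a)), collapse = ","),
        paste(sort(ad), collapse = ";"), sep = "|")
}

## --- parsing and writing ---------------------------------------------------

parse_tokens <- function(toks, neg_prefix, line) {
  bad <- grepl("[|$@()]", sub(paste0("^\\", neg_prefix), "", toks))
  if (any(bad))
    stop(sprintf("parse error at line %d, token %d: malformed token %s",
                 line, which(bad)[1], sQuote(toks[bad][1])), call. = FALSE)
  sign <- ifelse(startsWith(toks, neg_prefix), -1L, 1L)
  id <- sub(paste0("^\\", neg_prefix), "", toks)
  if (any(!nzchar(id)))
    stop(sprintf("parse error at line %d: empty gene token", line), call. = FALSE)
  list(id = id, sign = sign)
}

#' Parse a gene-order text into a chromosome structure
#'
#' Two dialects are supported.  `"grimm"`: an optional `>name` header line,
#' then one chromosome per line of whitespace-separated tokens with a leading
#' `-` for the reverse strand, terminated by `$` (linear) or `@` (circular).
#' `"table1"`: one structure on one line, chromosomes separated by `|`, a
#' leading `*` for the complementary strand and a trailing `(L)` or `(C)`
#' topology marker (defaulting to linear when absent).
#'
#' @param text character scalar or vector of lines.
#' @param dialect `"grimm"` or `"table1"`.
#' @param name structure name (overridden by a `>` header if present).
#' @return a `chrom_structure`.
#' @export
parse_structure <- function(text, dialect = c("grimm", "table1"), name = "") {
  dialect <- match.arg(dialect)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  if (dialect == "grimm") {
    chrs <- list()
    ln <- 0L
    for (raw in lines) {
      ln <- ln + 1L
      line <- trimws(raw)
      if (!nzchar(line) || startsWith(line, "#")) next
      if (startsWith(line, ">")) { name <- trimws(sub("^>", "", line)); next }
      toks <- strsplit(line, "[[:space:]]+")[[1]]
      term <- toks[length(toks)]
      if (!term %in% c("$", "@"))
        stop(sprintf("parse error at line %d: chromosome must end with $ or @", ln),
             call. = FALSE)
      toks <- toks[-length(toks)]
      if (length(toks) == 0L)
        stop(sprintf("parse error at line %d: empty chromosome", ln), call. = FALSE)
      tk <- parse_tokens(toks, "-", ln)
      chrs[[length(chrs) + 1L]] <-
        chromosome(ifelse(tk$sign < 0, paste0("-", tk$id), tk$id), term == "@")
    }
    chrom_structure(chrs, name)
  } else {
    body <- paste(lines[nzchar(trimws(lines))], collapse = " ")
    segs <- strsplit(body, "|", fixed = TRUE)[[1]]
    chrs <- list()
    for (seg in segs) {
      seg <- trimws(seg)
      if (!nzchar(seg)) next
      circ <- FALSE
      if (grepl("\\((C|L)\\)\\s*$", seg)) {
        circ <- grepl("\\(C\\)\\s*$", seg)
        seg <- trimws(sub("\\((C|L)\\)\\s*$", "", seg))
      }
      toks <- strsplit(seg, "[[:space:]]+")[[1]]
      if (length(toks) == 0L || !nzchar(toks[1]))
        stop("parse error: empty chromosome segment", call. = FALSE)
      tk <- parse_tokens(toks, "*", 1L)
      chrs[[length(chrs) + 1L]] <-
        chromosome(ifelse(tk$sign < 0, paste0("-", tk$id), tk$id), circ)
    }
    chrom_structure(chrs, name)
  }
}

#' Write a chromosome structure as text
#'
#' Output is canonical (see [canonical_structure()]) so that writing is
#' deterministic and `parse_structure(write_structure(s))` returns a structure
#' equal to `s`.
#'
#' @param s a `chrom_structure`.
#' @param dialect `"grimm"` or `"table1"`.
#' @return a character scalar.
#' @export
write_structure <- function(s, dialect = c("grimm", "table1")) {
  dialect <- match.arg(dialect)
  s <- canonical_structure(s)
  if (dialect == "grimm") {
    header <- paste0(">", s$name)
    body <- vapply(s$chrs, function(ch)
      paste(c(signed_tokens(ch), if (ch$circular) "@" else "$"), collapse = " "),
      "")
    paste(c(header, body), collapse = "\n")
  } else {
    segs <- vapply(s$chrs, function(ch) {
      tok <- ifelse(ch$sign < 0, paste0("*", ch$id), ch$id)
      paste(paste(tok, collapse = " "), if (ch$circular) "(C)" else "(L)")
    }, "")
    paste(segs, collapse = " | ")
  }
}

## --- gene and adjacency views ---------------------------------------------

#' Genes of a structure
#' @param s a `chrom_structure`.
#' @return character vector of gene ids ("family" or "family.j").
#' @export
structure_genes <- function(s)
  as.character(unlist(lapply(s$chrs, `[[`, "id"), use.names = FALSE))

ext_head <- function(id, sign) paste0(id, ifelse(sign > 0, ":2", ":1"))
ext_tail <- function(id, sign) paste0(id, ifelse(sign > 0, ":1", ":2"))

adj_key <- function(e1, e2) {
  ifelse(e1 < e2, paste(e1, e2, sep = "~"), paste(e2, e1, sep = "~"))
}

#' Adjacency set of a structure
#'
#' Each adjacency is a glued pair of gene extremities, encoded as the sorted
#' pair of extremity ids `"gene:1"`/`"gene:2"` joined by `~`.  Telomeric
#' extremities appear in no adjacency.
#'
#' @param s a `chrom_structure`.
#' @return character vector of adjacency keys.
#' @export
structure_adjacencies <- function(s) {
  out <- character(0)
  for (ch in s$chrs) {
    n <- length(ch$id)
    if (n > 1L) {
      e_out <- ext_head(ch$id, ch$sign)
      e_in <- ext_tail(ch$id, ch$sign)
      out <- c(out, adj_key(e_out[-n], e_in[-1]))
    }
    if (ch$circular) {
      e_last <- ext_head(ch$id[n], ch$sign[n])
      e_first <- ext_tail(ch$id[1], ch$sign[1])
      out <- c(out, adj_key(e_last, e_first))
    }
  }
  out
}

## An adjset is the surgical representation: list(genes = character ids,
## adj = character adjacency keys).  Everything the rearrangement operations
## need is encoded there; chromosomes are recovered by walking.

#' @rdname structure_adjacencies
#' @export
as_adjset <- function(s) {
  list(genes = sort(structure_genes(s)), adj = sort(structure_adjacencies(s)),
       name = s$name)
}

adjset_key <- function(x)
  paste(paste(x$genes, collapse = ","), paste(sort(x$adj), collapse = ";"), sep = "|")

split_adj <- function(adj) strsplit(adj, "~", fixed = TRUE)

ext_gene <- function(e) sub(":[12]$", "", e)
ext_other <- function(e) {
  ifelse(endsWith(e, ":1"), paste0(ext_gene(e), ":2"), paste0(ext_gene(e), ":1"))
}

#' Rebuild a chromosome structure from an adjacency set
#'
#' @param x list with `genes` and `adj` as produced by [as_adjset()].
#' @param name structure name.
#' @return a `chrom_structure`.
#' @export
adjset_to_structure <- function(x, name = x$name %||% "") {
  genes <- x$genes
  nbr <- new.env(parent = emptyenv())
  for (p in split_adj(x$adj)) {
    assign(p[1], p[2], envir = nbr)
    assign(p[2], p[1], envir = nbr)
  }
  seen <- new.env(parent = emptyenv())
  chrs <- list()
  walk <- function(start, circular) {
    ids <- character(0); sgn <- integer(0)
    e <- start
    repeat {
      g <- ext_gene(e)
      assign(g, TRUE, envir = seen)
      ids <- c(ids, g)
      sgn <- c(sgn, if (endsWith(e, ":1")) 1L else -1L)
      e2 <- ext_other(e)
      nxt <- if (exists(e2, envir = nbr, inherits = FALSE)) get(e2, envir = nbr) else NULL
      if (is.null(nxt)) return(chromosome(ifelse(sgn < 0, paste0("-", ids), ids), FALSE))
      if (ext_gene(nxt) == ext_gene(start) && circular)
        return(chromosome(ifelse(sgn < 0, paste0("-", ids), ids), TRUE))
      if (exists(ext_gene(nxt), envir = seen, inherits = FALSE))
        return(chromosome(ifelse(sgn < 0, paste0("-", ids), ids), TRUE))
      e <- nxt
    }
  }
  ## linear chromosomes: start from telomeric extremities
  all_ext <- c(paste0(genes, ":1", recycle0 = TRUE),
               paste0(genes, ":2", recycle0 = TRUE))
  free <- all_ext[!vapply(all_ext, exists, TRUE, envir = nbr, inherits = FALSE)]
  free_g <- ext_gene(free)
  for (e in sort(free)) {
    if (exists(ext_gene(e), envir = seen, inherits = FALSE)) next
    chrs[[length(chrs) + 1L]] <- walk(e, circular = FALSE)
  }
  ## remaining genes lie on circles
  for (g in genes) {
    if (exists(g, envir = seen, inherits = FALSE)) next
    chrs[[length(chrs) + 1L]] <- walk(paste0(g, ":1"), circular = TRUE)
  }
  canonical_structure(chrom_structure(chrs, name))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
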
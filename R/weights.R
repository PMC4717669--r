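## ---------------------------------------------------------------------------
## Operation weights.  Six operations transform one structure into another:
## double-cut-and-paste, sesqui-cut-and-paste, cut, join, deletion of a
## maximal region of genes private to the source ("a-region deletion") and
## insertion of a region of genes private to the target ("b-region
## insertion", equivalently deletion of a b-node from the common graph; its
## weight is the symbol c of the exactness condition d <= c <= 2d).
## ---------------------------------------------------------------------------

.wkinds <- c("double", "sesqui", "cut", "join", "del_a", "ins_b")

#' Operation weight scheme
#'
#' The two named patterns order the weights by an inexact (non-strict)
#' descent.  Circular pattern: b-region insertion, sesqui, the two
#' cut-and-join directions, double, a-region deletion.  Linear pattern:
#' b-region insertion, double, sesqui, the two cut-and-join directions,
#' a-region deletion.  The default values assign the printed descent
#' 1.5, 1.2, 1.1, 1, 0.9, 0.8 along the pattern order.
#'
#' @param pattern `"circular"`, `"linear"` or `"none"`.
#' @param double,sesqui,cut,join,del_a,ins_b optional positive weights
#'   overriding the pattern defaults.
#' @return a `weight_scheme` object (named numeric weights plus pattern).
#' @export
weight_scheme <- function(pattern = c("circular", "linear", "none"),
                          double = NULL, sesqui = NULL, cut = NULL,
                          join = NULL, del_a = NULL, ins_b = NULL) {
  pattern <- match.arg(pattern)
  w <- switch(pattern,
    circular = c(double = 0.9, sesqui = 1.2, cut = 1.0, join = 1.1,
                 del_a = 0.8, ins_b = 1.5),
    linear   = c(double = 1.2, sesqui = 1.1, cut = 1.0, join = 0.9,
                 del_a = 0.8, ins_b = 1.5),
    none     = c(double = 1, sesqui = 1, cut = 1, join = 1,
                 del_a = 1, ins_b = 1))
  ov <- list(double = double, sesqui = sesqui, cut = cut, join = join,
             del_a = del_a, ins_b = ins_b)
  for (k in names(ov)) if (!is.null(ov[[k]])) w[[k]] <- as.numeric(ov[[k]])
  obj <- structure(list(w = w, pattern = pattern), class = "weight_scheme")
  viol <- validate_weights(obj)
  if (any(grepl("non-positive", viol))) stop(paste(viol, collapse = "; "))
  obj
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat("weight scheme (", x$pattern, " pattern):\n", sep = "")
  print(x$w)
  v <- validate_weights(x)
  if (length(v)) cat("violations:", paste(v, collapse = "; "), "\n")
  cat("exactness class:", exactness_class(x), "\n")
  invisible(x)
}

op_weight <- function(w, kind) unname(w$w[[kind]])

#' Validate a weight scheme
#'
#' Checks positivity and, for the named patterns, the non-increasing descent
#' of the weights in the pattern order (the two cut-and-join directions
#' occupy a single tier).
#'
#' @param w a `weight_scheme`.
#' @return character vector of violations (empty when valid), with
#'   attributes `case2` (do five weights equal some d with d <= c <= 2d for
#'   the b-region insertion weight c?) and `heuristic`.
#' @export
validate_weights <- function(w) {
  v <- character(0)
  bad <- names(w$w)[!is.finite(w$w) | w$w <= 0]
  if (length(bad)) v <- c(v, paste("non-positive weight:", paste(bad, collapse = ", ")))
  edge_hi <- max(w$w[["cut"]], w$w[["join"]])
  edge_lo <- min(w$w[["cut"]], w$w[["join"]])
  tiers <- switch(w$pattern,
    circular = list(c(w$w[["ins_b"]], w$w[["sesqui"]]),
                    c(w$w[["sesqui"]], edge_hi),
                    c(edge_lo, w$w[["double"]]),
                    c(w$w[["double"]], w$w[["del_a"]])),
    linear = list(c(w$w[["ins_b"]], w$w[["double"]]),
                  c(w$w[["double"]], w$w[["sesqui"]]),
                  c(w$w[["sesqui"]], edge_hi),
                  c(edge_lo, w$w[["del_a"]])),
    none = list())
  for (t in tiers)
    if (t[1] < t[2] - 1e-12)
      v <- c(v, sprintf("pattern descent violated: %.4g < %.4g", t[1], t[2]))
  d <- w$w[["double"]]
  five_equal <- all(abs(w$w[.wkinds[.wkinds != "ins_b"]] - d) < 1e-12)
  cc <- w$w[["ins_b"]]
  case2 <- five_equal && cc >= d - 1e-12 && cc <= 2 * d + 1e-12
  attr(v, "case2") <- case2
  attr(v, "heuristic") <- !case2 && (w$pattern == "none" || length(v) > 0)
  v
}

## Exactness classification for a comparison of structures a, b under w:
## case 1 needs equal gene content and a named, satisfied pattern; case 2
## needs five equal weights d and d <= c <= 2d.
exactness_class <- function(w, equal_content = NA) {
  v <- validate_weights(w)
  if (w$pattern %in% c("circular", "linear") && length(v) == 0 &&
      (is.na(equal_content) || isTRUE(equal_content)))
    return("EXACT_CASE1")
  if (isTRUE(attr(v, "case2"))) return("EXACT_CASE2_ADDITIVE_d")
  "HEURISTIC"
}

#' Read or write a weight scheme as a YAML config
#'
#' @param path file path.
#' @return [read_weights()] returns a `weight_scheme`.
#' @export
read_weights <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(weight_scheme, c(list(pattern = cfg$pattern %||% "none"),
                           cfg[intersect(names(cfg), .wkinds)]))
}

#' @rdname read_weights
#' @param w a `weight_scheme`.
#' @export
write_weights <- function(w, path) {
  yaml::write_yaml(c(list(pattern = w$pattern), as.list(w$w)), path)
  invisible(path)
}
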
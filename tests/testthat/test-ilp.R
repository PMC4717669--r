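test_that("variable and constraint counts follow the closed forms", {
  ## two circular structures, 3 families x 2 paralogs: z = 3*4 = 12 with
  ## 3*(2+2) z-constraints; one adjacent pair per gene occurrence
  mk <- function(seed) {
    set.seed(seed)
    ids <- paste0(rep(1:3, each = 2), ".", rep(1:2, 3))
    ids <- sample(ids)
    chrom_structure(list(chromosome(ids, circular = TRUE)))
  }
  ilp <- build_matching_ilp(mk(1), mk(2))
  sz <- ilp_size(ilp)
  expect_identical(sz$z_vars, 12L)
  expect_identical(sz$z_cons, 12L)
  expect_identical(sz$x_vars_a, 6L)
  expect_identical(sz$x_vars, 12L)
  expect_identical(sz$x_cons, 24L)
  expect_identical(sz$y_vars, 12L)
  expect_identical(sz$up_vars, 24L)
  expect_identical(sz$total_vars,
                   sz$z_vars + sz$x_vars + sz$y_vars + sz$up_vars +
                     0L)  # single chromosome per side: hard cover rows, no w vars
})

test_that("linear chromosomes are rejected with a pointer to path closure", {
  a <- parse_structure(">a\ng1.1 g1.2 $")
  b <- parse_structure(">b\ng1.1 g1.2 @")
  expect_error(build_matching_ilp(a, b), "distance_with_paths")
})

test_that("without paralogs the ILP optimum equals the unit edit distance", {
  cases <- list(
    c(">a\ng1 g2 g3 @", ">b\ng1 -g2 g3 @"),
    c(">a\ng1 g2 @", ">b\ng1 @\ng2 @"),
    c(">a\ng1 x1 g2 @", ">b\ng1 g2 @"))
  for (cs in cases) {
    a <- parse_structure(cs[1]); b <- parse_structure(cs[2])
    r <- solve_paralog_matching(a, b)
    orc <- bfs_shortest_sequence(a, b, weight_scheme("none"))
    expect_equal(r$distance, orc$weight, info = cs[1])
  }
})

test_that("paralog matching equals the exhaustive bijection oracle", {
  oracle_par <- function(a, b) {
    ga <- structure_genes(a); gb <- structure_genes(b)
    Pa <- split(par_index(ga), gene_family(ga))
    Pb <- split(par_index(gb), gene_family(gb))
    fams <- intersect(names(Pa), names(Pb))
    partials <- function(pa, pb) {
      res <- list(data.frame(pa = integer(0), pb = integer(0)))
      rec <- function(i, used, rows) {
        if (i > length(pa)) { res[[length(res) + 1]] <<- rows; return(invisible()) }
        rec(i + 1, used, rows)
        for (j in seq_along(pb)) if (!used[j])
          rec(i + 1, replace(used, j, TRUE),
              rbind(rows, data.frame(pa = pa[i], pb = pb[j])))
      }
      rec(1, rep(FALSE, length(pb)), data.frame(pa = integer(0), pb = integer(0)))
      unique(res)
    }
    sets <- lapply(fams, function(k) partials(Pa[[k]], Pb[[k]]))
    combos <- list()
    rec2 <- function(fi, bij) {
      if (fi > length(fams)) {
        combos[[length(combos) + 1]] <<- bij
        return(invisible())
      }
      for (s in sets[[fi]]) { bij[[fams[fi]]] <- s; rec2(fi + 1, bij) }
    }
    rec2(1, list())
    ## pass 1: cheap upper bounds from the transformation give a tight
    ## incumbent; pass 2: bounded exact searches
    rels <- lapply(combos, function(bij) relabel_matched(a, b, bij))
    ubs <- vapply(rels, function(rel)
      transform_to_final(rel$a, rel$b, weight_scheme("none"))$total_weight, 0)
    best <- min(ubs)
    for (i in order(ubs)) {
      o <- bfs_shortest_sequence(rels[[i]]$a, rels[[i]]$b, weight_scheme("none"),
                                 max_weight = min(best, ubs[i]) + 0.01)
      if (o$found) best <- min(best, o$weight)
    }
    best
  }
  cases <- list(
    c(">a\ng1.1 g2.1 g1.2 g2.2 @", ">b\ng1.1 g1.2 g2.1 g2.2 @"),
    c(">a\ng1.1 g1.2 @", ">b\ng1.1 @"),
    c(">a\ng1.1 -g1.2 g2.1 @", ">b\ng1.1 g2.1 g1.2 @"))
  for (cs in cases) {
    a <- parse_structure(cs[1]); b <- parse_structure(cs[2])
    r <- solve_paralog_matching(a, b)
    expect_equal(r$distance, oracle_par(a, b), info = cs[1])
  }
})

test_that("identical structures with identical labels give identity matching", {
  a <- parse_structure(">a\ng1.1 g1.2 g2.1 @")
  r <- solve_paralog_matching(a, a)
  expect_equal(r$distance, 0)
  for (k in names(r$bijections)) {
    rows <- r$bijections[[k]]
    expect_true(all(rows$pa == rows$pb))
  }
})

test_that("zero-similarity pairs are never matched", {
  a <- parse_structure(">a\ng1.1 g1.2 @")
  b <- parse_structure(">b\ng1.1 g1.2 @")
  sim <- data.frame(family = "g1", pa = c(1L, 1L, 2L, 2L), pb = c(1L, 2L, 1L, 2L),
                    sim = c(0, 1, 1, 0))
  r <- solve_paralog_matching(a, b, sim)
  rows <- r$bijections[["g1"]]
  expect_false(any(rows$pa == rows$pb))
})

test_that("close_paths circularizes exactly the linear chromosomes", {
  s <- parse_structure(">s\ng1 g2 $\ng3 $\ng4 @")
  r <- close_paths(s)
  expect_identical(r$n_paths, 2L)
  expect_true(all(vapply(r$closed$chrs, `[[`, TRUE, "circular")))
  r2 <- close_paths(r$closed)
  expect_identical(r2$n_paths, 0L)
})

test_that("the path-closing distance respects its error bound", {
  a <- parse_structure(">a\ng1 g2 $")
  b <- parse_structure(">b\ng1 g2 @")
  r <- distance_with_paths(a, b)
  expect_identical(r$n1, 1L)
  expect_identical(r$error_bound, 2)
  orc <- bfs_shortest_sequence(a, b, weight_scheme("none"))
  expect_lte(abs(r$value - orc$weight), r$error_bound)
  ## all-circular input reduces to the plain matching value with zero bound
  r0 <- distance_with_paths(b, b)
  expect_identical(r0$value, 0)
  expect_identical(r0$error_bound, 0)
})

test_that("breakpoint matching equals the exhaustive bijection minimum", {
  bp_oracle <- function(a, b) {
    ga <- structure_genes(a); gb <- structure_genes(b)
    Pa <- split(par_index(ga), gene_family(ga))
    Pb <- split(par_index(gb), gene_family(gb))
    fams <- intersect(names(Pa), names(Pb))
    partials <- function(pa, pb) {
      res <- list(data.frame(pa = integer(0), pb = integer(0)))
      rec <- function(i, used, rows) {
        if (i > length(pa)) { res[[length(res) + 1]] <<- rows; return(invisible()) }
        rec(i + 1, used, rows)
        for (j in seq_along(pb)) if (!used[j])
          rec(i + 1, replace(used, j, TRUE),
              rbind(rows, data.frame(pa = pa[i], pb = pb[j])))
      }
      rec(1, rep(FALSE, length(pb)), data.frame(pa = integer(0), pb = integer(0)))
      res
    }
    sets <- lapply(fams, function(k) partials(Pa[[k]], Pb[[k]]))
    best <- Inf
    rec2 <- function(fi, bij) {
      if (fi > length(fams)) {
        rel <- relabel_matched(a, b, bij)
        best <<- min(best, breakpoint_distance(rel$a, rel$b))
        return(invisible())
      }
      for (s in sets[[fi]]) { bij[[fams[fi]]] <- s; rec2(fi + 1, bij) }
    }
    rec2(1, list())
    best
  }
  cases <- list(
    c(">a\ng1.1 g2.1 g1.2 @", ">b\ng1.1 g1.2 g2.1 @"),
    c(">a\ng1.1 g1.2 $", ">b\ng1.1 -g1.2 $"),
    c(">a\ng1.1 $", ">b\nh1.1 $"))
  for (cs in cases) {
    a <- parse_structure(cs[1]); b <- parse_structure(cs[2])
    r <- breakpoint_matching(a, b)
    expect_equal(r$distance, bp_oracle(a, b), info = cs[1])
  }
  ## disjoint content: distance is the total gene count, nothing matched
  a <- parse_structure(">a\ng1.1 $"); b <- parse_structure(">b\nh1.1 $")
  r <- breakpoint_matching(a, b)
  expect_equal(r$distance, 2)
})
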
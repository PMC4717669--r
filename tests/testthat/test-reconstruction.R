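test_that("distance matrices are symmetric with zero diagonal", {
  s1 <- parse_structure(">s1\ng1 g2 g3 @")
  s2 <- parse_structure(">s2\ng1 -g2 g3 @")
  s3 <- parse_structure(">s3\ng3 g1 g2 @")
  dm <- distance_matrix(list(s1, s2, s3), "breakpoint")
  expect_identical(unname(diag(dm)), c(0, 0, 0))
  expect_identical(dm, t(dm))
  dm2 <- distance_matrix(list(s1, s1), "biological")
  expect_identical(unname(dm2[1, 2]), 0)
})

test_that("matrix cells equal independent per-pair recomputation", {
  rows <- read_table1()
  piro <- rows[c("Babesia_bovis", "Theileria_parva", "Theileria_annulata")]
  dm <- distance_matrix(piro, "breakpoint")
  for (i in 1:2) for (j in (i + 1):3)
    expect_identical(dm[i, j],
                     as.numeric(breakpoint_distance(piro[[i]], piro[[j]])))
})

test_that("average-linkage recovers an ultrametric topology", {
  D <- matrix(c(0, 2, 8, 8,
                2, 0, 8, 8,
                8, 8, 0, 4,
                8, 8, 4, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- build_tree_upgma(D)
  expect_s3_class(tr, "phylo")
  ## a+b and c+d are cherries
  pairs <- ape::prop.part(tr)
  grps <- lapply(pairs, function(p) sort(tr$tip.label[p]))
  expect_true(list(c("a", "b")) %in% grps || list(c("c", "d")) %in% grps)
})

test_that("two structures give a single-edge tree with the pairwise weight", {
  s1 <- parse_structure(">s1\ng1 g2 $")
  s2 <- parse_structure(">s2\ng1 -g2 $")
  at <- steiner_first(list(s1, s2), "breakpoint")
  expect_equal(at$weight, breakpoint_distance(s1, s2))
})

test_that("identical terminals reconstruct with zero weight", {
  s <- parse_structure(">s\ng1 g2 g3 @")
  at <- steiner_first(list(s, s, s, s), "breakpoint")
  expect_identical(at$weight, 0)
  z <- zelikovsky_second(list(s, s, s), "breakpoint")
  expect_identical(z$weight, 0)
})

test_that("the median of an identical triple is the structure itself", {
  s <- parse_structure(">s\ng1 g2 @")
  r <- median_three(s, s, s, "breakpoint")
  expect_equal(r$d_z, 0)
  expect_true(structures_equal(r$structure, s))
  rb <- median_three(s, s, s, "biological")
  expect_equal(rb$d_z, 0)
})

test_that("breakpoint medians match the exhaustive enumeration bound", {
  set.seed(500)
  genes <- c("g1", "g2", "g3")
  univ <- all_structures(genes, exact = FALSE)
  for (i in 1:4) {
    tri <- sample(univ, 3)
    r <- median_three(tri[[1]], tri[[2]], tri[[3]], "breakpoint")
    ## exhaustive check: no structure does better
    best <- min(vapply(univ, function(s)
      breakpoint_distance(s, tri[[1]]) + breakpoint_distance(s, tri[[2]]) +
        breakpoint_distance(s, tri[[3]]), 0))
    expect_equal(r$d_z, best)
  }
})

test_that("the biological median heuristic is bounded by its endpoints", {
  set.seed(501)
  w <- weight_scheme("none")
  cfg <- evolution_config(n_genes = 3, circular_prob = 1)
  for (i in 1:3) {
    a <- random_structure(cfg); b <- random_structure(cfg); c <- random_structure(cfg)
    r <- median_three(a, b, c, "biological", w)
    f <- function(x, y) biological_distance(x, y, w)$symmetric
    ## endpoints are candidate medians, so the heuristic is at most the best
    ## endpoint score, in particular d(a,b) + min(d(a,c), d(b,c))
    expect_lte(r$d_z, f(a, b) + min(f(a, c), f(b, c)) + 1e-9)
    ## and it can never beat the exhaustive optimum over the universe
    univ <- all_structures(c("g1", "g2", "g3"), exact = FALSE)
    best <- min(vapply(univ, function(s) f(s, a) + f(s, b) + f(s, c), 0))
    expect_gte(r$d_z, best - 1e-9)
  }
})

test_that("greedy descent never increases the arrangement weight", {
  set.seed(502)
  cfg <- evolution_config(n_genes = 3, circular_prob = 1, n_events = 1)
  sim <- simulate_evolution(random_structure(cfg),
                            "((A:1,B:1):1,(C:1,D:1):1);", cfg)
  at <- steiner_first(sim$leaves, "biological")
  rt <- descent_refine(at)
  expect_lte(rt$weight, at$weight + 1e-9)
  ## a second pass is already at the local minimum
  rt2 <- descent_refine(rt)
  expect_equal(rt2$weight, rt$weight)
})

test_that("one-way rooting matches an exhaustive root scan", {
  set.seed(503)
  cfg <- evolution_config(n_genes = 3, circular_prob = 1, n_events = 1)
  sim <- simulate_evolution(random_structure(cfg), "((A:1,B:1):1,C:1);", cfg)
  at <- steiner_first(sim$leaves, "biological")
  rooted <- root_by_oneway(at)
  expect_true(!is.null(rooted$oneway_total))
  ## rerooting again is stable
  r2 <- root_by_oneway(rooted)
  expect_equal(r2$oneway_total, rooted$oneway_total)
})
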
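test_that("identical structures need no operations", {
  for (txt in list(">x\ng1 g2 g3 @", ">x\ng1 -g2 $\ng3 $", ">x\nx @")) {
    s <- parse_structure(txt)
    sc <- transform_to_final(s, s, weight_scheme("none"))
    expect_identical(sc$length, 0L)
    expect_identical(sc$total_weight, 0)
  }
})

test_that("a single internal inversion costs one double-cut-and-paste", {
  a <- parse_structure(">a\ng1 g2 g3 $")
  b <- parse_structure(">b\ng1 -g2 g3 $")
  sc <- transform_to_final(a, b, weight_scheme("none"))
  expect_identical(sc$length, 1L)
  expect_identical(sc$ops[[1]]$kind, "DOUBLE")
  orc <- bfs_shortest_sequence(a, b, weight_scheme("none"))
  expect_equal(sc$total_weight, orc$weight)
})

test_that("content differences are handled by region deletion and insertion", {
  a <- parse_structure(">a\ng1 x g2 $")
  b <- parse_structure(">b\ng1 y g2 $")
  sc <- transform_to_final(a, b, weight_scheme("none"))
  kinds <- vapply(sc$ops, `[[`, "", "kind")
  expect_true("DELETE_REGION" %in% kinds)
  expect_true("INSERT_REGION" %in% kinds)
  expect_identical(sc$length, 2L)
})

test_that("scenarios replay to the target structure", {
  set.seed(100)
  for (i in 1:60) {
    p <- random_small_pair(sample(4:6, 1))
    sc <- transform_to_final(p$a, p$b, weight_scheme("circular"))
    expect_true(structures_equal(replay_scenario(sc, p$a), p$b))
    expect_equal(sc$total_weight, sum(vapply(sc$ops, `[[`, 0, "weight")))
  }
})

test_that("small random instances match the oracle in the exact regimes", {
  set.seed(101)
  w2 <- weight_scheme("none", ins_b = 1.5)
  wl <- weight_scheme("linear")
  for (i in 1:15) {
    p <- random_small_pair(4)
    sc <- transform_to_final(p$a, p$b, w2)
    orc <- bfs_shortest_sequence(p$a, p$b, w2, max_weight = sc$total_weight + 0.01)
    expect_true(orc$found)
    expect_lte(sc$total_weight, orc$weight + 1 + 1e-9)
    expect_gte(sc$total_weight, orc$weight - 1e-9)
    if (setequal(structure_genes(p$a), structure_genes(p$b))) {
      scl <- transform_to_final(p$a, p$b, wl)
      ol <- bfs_shortest_sequence(p$a, p$b, wl, max_weight = scl$total_weight + 0.01,
                                  mode = "length_then_weight")
      expect_equal(scl$total_weight, ol$weight)
    }
  }
})

test_that("distance is monotone under adding one private gene", {
  set.seed(102)
  w <- weight_scheme("none")
  maxw <- max(w$w)
  for (i in 1:10) {
    p <- random_small_pair(4)
    base <- transform_to_final(p$a, p$b, w)$total_weight
    a2 <- p$a
    a2$chrs[[1]] <- chromosome(c(signed_tokens(a2$chrs[[1]]), "zz"),
                               a2$chrs[[1]]$circular)
    a2 <- chrom_structure(a2$chrs)
    ext <- transform_to_final(a2, p$b, w)$total_weight
    expect_gte(ext, base - maxw - 1e-9)
  }
})

test_that("biological distance symmetrizes the two directions", {
  a <- parse_structure(">a\ng1 x g2 $")
  b <- parse_structure(">b\ng1 g2 $")
  r <- biological_distance(a, b, weight_scheme("none", ins_b = 1.5))
  expect_equal(r$symmetric, (r$one_way_ab + r$one_way_ba) / 2)
  expect_identical(r$exactness_class, "EXACT_CASE2_ADDITIVE_d")
  r0 <- biological_distance(a, a, weight_scheme("circular"))
  expect_identical(r0$symmetric, 0)
  expect_identical(r0$exactness_class, "EXACT_CASE1")
})

test_that("triangle inequality holds for the symmetric distance", {
  set.seed(103)
  w <- weight_scheme("none", ins_b = 1.3)
  for (i in 1:8) {
    tri <- list(random_small_pair(4)$a, random_small_pair(4)$a,
                random_small_pair(4)$a)
    d <- function(x, y) biological_distance(x, y, w)$symmetric
    d12 <- d(tri[[1]], tri[[2]]); d13 <- d(tri[[1]], tri[[3]])
    d23 <- d(tri[[2]], tri[[3]])
    expect_lte(d12, d13 + d23 + 1e-9)
  }
})
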
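test_that("the two independent searches agree on unit-weight instances", {
  set.seed(200)
  w <- weight_scheme("none")
  for (i in 1:12) {
    p <- random_small_pair(4)
    orc <- bfs_shortest_sequence(p$a, p$b, w, max_weight = 8)
    ops <- iddfs_min_ops(p$a, p$b, w, max_depth = 6L)
    expect_equal(orc$length, ops)
  }
})

test_that("oracle cost is symmetric under equal weights", {
  set.seed(201)
  w <- weight_scheme("none")
  for (i in 1:8) {
    p <- random_small_pair(5)
    f <- bfs_shortest_sequence(p$a, p$b, w, max_weight = 8)
    r <- bfs_shortest_sequence(p$b, p$a, w, max_weight = 8)
    expect_equal(f$weight, r$weight)
  }
})

test_that("structure enumeration is canonical and duplicate-free", {
  u1 <- all_structures("g1")
  expect_length(u1, 2L)   # one linear, one circular single-gene chromosome
  u2 <- all_structures(c("g1", "g2"), exact = FALSE)
  keys <- vapply(u2, structure_key, "")
  expect_identical(anyDuplicated(keys), 0L)
  expect_true(any(vapply(u2, function(s) length(s$chrs) == 0L, TRUE)))
})

test_that("brute-force Steiner agrees with simple certificates", {
  s <- parse_structure(">s\ng1 g2 $")
  expect_identical(brute_force_steiner(list(s, s, s), "breakpoint",
                                       c("g1", "g2")), 0)
  t2 <- parse_structure(">t\ng1 -g2 $")
  d <- breakpoint_distance(s, t2)
  expect_equal(brute_force_steiner(list(s, t2), "breakpoint", c("g1", "g2")), d)
})

test_that("Steiner optimum never exceeds the star through any candidate", {
  set.seed(202)
  dmat <- NULL
  genes <- c("g1", "g2", "g3")
  univ <- all_structures(genes, exact = FALSE)
  for (i in 1:5) {
    terms <- sample(univ, 4)
    opt <- brute_force_steiner(terms, "breakpoint", genes)
    hub <- univ[[sample(seq_along(univ), 1)]]
    star <- sum(vapply(terms, function(s) breakpoint_distance(s, hub), 0))
    expect_lte(opt, star + 1e-9)
  }
})
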
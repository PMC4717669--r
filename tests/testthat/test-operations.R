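test_that("adjacency surgery round-trips", {
  x <- as_adjset(parse_structure(">a\ng1 g2 g3 $"))
  ad <- x$adj[1]
  expect_identical(op_join(op_cut(x, ad), split_adj(ad)[[1]][1],
                           split_adj(ad)[[1]][2])$adj, x$adj)
  ## dcj with pairing 1 then reversing via pairing on the new pair restores
  y <- op_dcj(x, x$adj[1], x$adj[2], 1L)
  expect_length(y$adj, length(x$adj))
})

test_that("region deletion rejoins flanks and insertion is its inverse", {
  x <- as_adjset(parse_structure(">a\ng1 x1 x2 g2 $"))
  y <- op_delete_region(x, c("x1", "x2"))
  expect_true(adj_key(ext_head("g1", 1L), ext_tail("g2", 1L)) %in% y$adj)
  z <- op_insert_region(y, c("x1", "x2"), c(1L, 1L),
                        adj_key(ext_head("g1", 1L), ext_tail("g2", 1L)))
  expect_identical(z$adj, x$adj)
  expect_identical(z$genes, x$genes)
})

test_that("special runs wrap around circular chromosomes", {
  x <- as_adjset(parse_structure(">a\nx1 g1 g2 x2 @"))
  runs <- special_runs(x, c("g1", "g2"))
  expect_length(runs, 1L)
  expect_setequal(runs[[1]], c("x1", "x2"))
})

test_that("moves never cut inside a private region", {
  a <- as_adjset(parse_structure(">a\ng1 x1 x2 g2 $"))
  b <- as_adjset(parse_structure(">b\ng1 g2 $"))
  mvs <- enumerate_moves(a, b, weight_scheme("none"))
  forbidden <- adj_key(ext_head("x1", 1L), ext_tail("x2", 1L))
  for (mv in mvs) {
    if (mv$kind == "cut") expect_false(identical(mv$adj, forbidden))
    if (mv$kind == "double") expect_false(forbidden %in% c(mv$a1, mv$a2))
  }
})

test_that("standard moves cannot circularize an excised private region", {
  ## cutting out x1 x2 and closing it into a circle is an unnatural variant
  a <- as_adjset(parse_structure(">a\ng1 x1 x2 g2 @"))
  b <- as_adjset(parse_structure(">b\ng1 g2 @"))
  mvs <- enumerate_moves(a, b, weight_scheme("none"))
  spa <- attr(mvs, "special_a")
  for (mv in mvs) {
    y <- apply_move(a, mv, spa)
    if (is.null(y)) next
    expect_identical(count_special_circles(y, spa), 0L)
  }
})
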
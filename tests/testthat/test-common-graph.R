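test_that("identical circular structures give only final 2-circles", {
  a <- parse_structure(">a\ng1 g2 @")
  g <- build_common_graph(a, a)
  comps <- cg_components(g)
  expect_length(comps, 2L)
  expect_true(all(vapply(comps, function(c) comp_is_final(g, c), TRUE)))
})

test_that("a private gene between shared neighbours forms one special node", {
  a <- parse_structure(">a\ng1 x g2 $")
  b <- parse_structure(">b\ng1 g2 $")
  g <- build_common_graph(a, b)
  specs <- names(g$kind)[g$kind == "spec"]
  expect_length(specs, 1L)
  expect_identical(unname(g$side[specs]), "a")
  ## the b-edge joins the flanking extremities directly: a 2-circle with an
  ## a-node and no b-node
  comps <- cg_components(g)
  types <- vapply(comps, function(c) classify_component(g, c), "")
  expect_true("a-circle" %in% types)
})

test_that("an all-private circular chromosome becomes a special loop node", {
  a <- parse_structure(">a\nx @")
  b <- chrom_structure(list(), "b")
  g <- build_common_graph(a, b)
  comps <- cg_components(g)
  expect_length(comps, 1L)
  expect_identical(classify_component(g, comps[[1]]), "a_loop")
  g2 <- build_common_graph(b, a)
  expect_identical(classify_component(g2, cg_components(g2)[[1]]), "loop")
})

test_that("isolated private nodes classify by source", {
  a <- parse_structure(">a\ng1 $")
  b <- parse_structure(">b\ng1 $\ny $")
  g <- build_common_graph(a, b)
  types <- vapply(cg_components(g), function(c) classify_component(g, c), "")
  expect_true("2a'" %in% types)    # isolated special b-node
  g2 <- build_common_graph(b, a)
  types2 <- vapply(cg_components(g2), function(c) classify_component(g2, c), "")
  expect_true("2b'" %in% types2)
})

test_that("a path with only two hanging edges is type 2'", {
  ## both private flanks attach to the same extremity of the shared gene
  a <- parse_structure(">a\nx g1 $")
  b <- parse_structure(">b\ny g1 $")
  g <- build_common_graph(a, b)
  types <- vapply(cg_components(g), function(c) classify_component(g, c), "")
  expect_true("2'" %in% types)
})

test_that("classification is total and parity-consistent on random pairs", {
  set.seed(421)
  w <- weight_scheme("none")
  for (i in 1:120) {
    p <- random_small_pair(sample(4:6, 1))
    st <- eng_new(p$a, p$b, w)
    step1(st); step2(st)
    for (e in engine_components(st)) {
      expect_true(is.character(e$type) && nzchar(e$type))
      if (!is.null(e$comp) && e$comp$shape == "path") {
        L <- comp_length(st$g, e$comp)
        if (e$type %in% c("1a", "1b", "2a", "2b", "3a", "3b", "3a'", "3b'"))
          expect_identical(L %% 2L, 1L, label = e$type)
        if (e$type %in% c("1_a", "1_b", "2", "3"))
          expect_identical(L %% 2L, 0L, label = e$type)
      }
    }
  }
})

test_that("conventional-node degree never exceeds one per source", {
  set.seed(77)
  for (i in 1:40) {
    p <- random_small_pair(6)
    g <- build_common_graph(p$a, p$b)
    for (v in names(g$kind)[g$kind == "conv"]) {
      expect_lte(length(cg_edges_of(g, v, "a")), 1L)
      expect_lte(length(cg_edges_of(g, v, "b")), 1L)
    }
  }
})
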
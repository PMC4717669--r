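test_that("breakpoint distance is zero between equal structures", {
  s <- parse_structure(">x\ng1 g2 g3 @")
  expect_identical(breakpoint_distance(s, s), 0L)
})

test_that("breakpoint distance matches a direct adjacency-set comparison", {
  rows <- read_table1()
  tp <- rows[["Theileria_parva"]]
  ta <- rows[["Theileria_annulata"]]
  ## independent oracle: symmetric difference of adjacency sets plus genes
  ## private to one structure
  oracle <- function(a, b) {
    xa <- as_adjset(a); xb <- as_adjset(b)
    length(setdiff(xa$adj, xb$adj)) + length(setdiff(xb$adj, xa$adj)) +
      length(setdiff(xa$genes, xb$genes)) + length(setdiff(xb$genes, xa$genes))
  }
  expect_identical(breakpoint_distance(tp, ta), oracle(tp, ta))
  ## annulata carries ls2, parva does not: the content term contributes
  expect_true("ls2" %in% structure_genes(ta))
  expect_false("ls2" %in% structure_genes(tp))
  expect_gt(breakpoint_distance(tp, ta), 0L)
  ## small closed-form case
  a <- parse_structure(">a\ng1 g2 $")
  b <- parse_structure(">b\ng1 $")
  expect_identical(breakpoint_distance(a, b), oracle(a, b))
  expect_identical(breakpoint_distance(a, b), 2L)
})

test_that("breakpoint distance is symmetric on random pairs", {
  set.seed(300)
  for (i in 1:20) {
    p <- random_small_pair(6)
    expect_identical(breakpoint_distance(p$a, p$b),
                     breakpoint_distance(p$b, p$a))
  }
})
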
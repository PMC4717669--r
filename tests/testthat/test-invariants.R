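test_that("the final form has all-zero invariants", {
  s <- parse_structure(">s\ng1 g2 g3 @")
  iv <- compute_invariants(s, s, weight_scheme("none"))
  expect_identical(iv$B, 0L)
  expect_identical(iv$S, 0L)
  expect_identical(iv$B_prime, 0L)
  expect_identical(iv$n_ops, 0L)
  expect_identical(iv$C, 0)
})

test_that("a circle with b-nodes only contributes to B'", {
  a <- parse_structure(">a\ng1 g2 @")
  b <- parse_structure(">b\ng1 y g2 @")
  iv <- compute_invariants(a, b, weight_scheme("none", ins_b = 1.5))
  expect_identical(iv$B_prime, 1L)
  expect_identical(iv$ops_bdel, 1L)
  expect_equal(iv$C, iv$total_weight)
})

test_that("the weight-formula decomposition holds on random instances", {
  set.seed(600)
  w2 <- weight_scheme("none", ins_b = 1.4)
  for (i in 1:40) {
    p <- random_small_pair(sample(4:6, 1))
    iv <- compute_invariants(p$a, p$b, w2)
    expect_identical(iv$ops_spec_decreasing, iv$B)
    expect_identical(iv$ops_step2, iv$S)
    expect_gte(iv$n, 0L)
    expect_lte(iv$n, 2L)
    expect_equal(iv$C, iv$total_weight)
    ## and the prediction matches the emitted scenario
    sc <- transform_to_final(p$a, p$b, w2)
    expect_equal(sc$total_weight, iv$total_weight)
  }
})
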
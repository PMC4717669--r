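test_that("pattern defaults satisfy the printed descent and validate", {
  for (p in c("circular", "linear")) {
    w <- weight_scheme(p)
    expect_length(validate_weights(w), 0L)
    expect_setequal(round(sort(unname(w$w)), 2), c(0.8, 0.9, 1, 1.1, 1.2, 1.5))
  }
})

test_that("equal weights are valid for both patterns and give case 2", {
  for (p in c("circular", "linear")) {
    w <- weight_scheme(p, double = 1, sesqui = 1, cut = 1, join = 1,
                       del_a = 1, ins_b = 1)
    v <- validate_weights(w)
    expect_length(v, 0L)
    expect_true(attr(v, "case2"))
  }
})

test_that("b-region insertion above twice d breaks case 2", {
  w <- weight_scheme("none", ins_b = 2.5)
  v <- validate_weights(w)
  expect_false(attr(v, "case2"))
  expect_identical(exactness_class(w), "HEURISTIC")
})

test_that("descent violations and non-positive weights are reported", {
  w <- weight_scheme("circular")
  w$w[["sesqui"]] <- 2.0   # above the insertion weight
  expect_true(length(validate_weights(w)) > 0L)
  expect_error(weight_scheme("none", double = -1), "non-positive")
})

test_that("weight schemes round-trip through yaml config files", {
  w <- weight_scheme("linear", cut = 0.95)
  f <- tempfile(fileext = ".yaml")
  write_weights(w, f)
  w2 <- read_weights(f)
  expect_equal(w2$w, w$w)
  expect_identical(w2$pattern, "linear")
})
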
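test_that("simulation is reproducible under a fixed seed", {
  cfg <- evolution_config(n_genes = 4, n_events = 2)
  set.seed(42); r1 <- random_structure(cfg)
  set.seed(42); r2 <- random_structure(cfg)
  expect_true(structures_equal(r1, r2))
  set.seed(43)
  s1 <- simulate_evolution(r1, "((A:1,B:1):1,C:1);", cfg)
  set.seed(43)
  s2 <- simulate_evolution(r1, "((A:1,B:1):1,C:1);", cfg)
  for (nm in names(s1$leaves))
    expect_true(structures_equal(s1$leaves[[nm]], s2$leaves[[nm]]))
})

test_that("zero events per edge copies the root everywhere", {
  cfg <- evolution_config(n_genes = 4, n_events = 0)
  set.seed(1)
  root <- random_structure(cfg)
  sim <- simulate_evolution(root, "((A:1,B:1):1,C:1);", cfg)
  for (s in sim$arrangement) expect_true(structures_equal(s, root))
})

test_that("leaf distances are bounded by events along the connecting path", {
  cfg <- evolution_config(n_genes = 5, n_events = 2, circular_prob = 1,
                          op_rates = c(double = 1, sesqui = 0, cut = 0,
                                       join = 0, del = 0, ins = 0))
  w <- weight_scheme("none")
  set.seed(7)
  for (rep in 1:5) {
    root <- random_structure(cfg)
    sim <- simulate_evolution(root, "(A:1,B:1);", cfg)
    d <- biological_distance(sim$leaves$A, sim$leaves$B, w)
    expect_lte(d$symmetric, 4 + 1e-9)  # two edges, two unit events each
  }
})

test_that("invalid configurations are rejected", {
  expect_error(evolution_config(op_rates = c(double = -1)), ">= 0")
  expect_error(evolution_config(circular_prob = 2))
})
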
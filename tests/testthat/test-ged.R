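scen7 <- scenario_costs(7)

test_that("pair_state classifies unordered pairs", {
  g <- foodweb(rbind(c("a", "b"), c("b", "c"), c("c", "b")), nodes = c("a", "b", "c", "d"))
  expect_equal(pair_state(g, "a", "b"), "forward")
  expect_equal(pair_state(g, "b", "a"), "backward")
  expect_equal(pair_state(g, "b", "c"), "both")
  expect_equal(pair_state(g, "a", "d"), "none")
  expect_error(pair_state(g, "a", "a"), "self-loops")
})

test_that("mapping cost prices each edit route correctly", {
  w <- foodweb(rbind(c("a", "b"), c("b", "c")), name = "w")
  idm <- node_mapping(pairs = stats::setNames(w$nodes, w$nodes))
  expect_equal(mapping_cost(w, w, idm, cost_scheme(0.9, 0.7, 0.3)), 0)

  # reversal priced min(flip, 2 * link): flip route vs delete+insert route
  g1 <- foodweb(rbind(c("a", "b")), name = "g1")
  g2 <- foodweb(rbind(c("b", "a")), name = "g2")
  m <- node_mapping(pairs = c(a = "a", b = "b"))
  expect_equal(mapping_cost(g1, g2, m, cost_scheme(0.75, 0.5, 0.25)), 0.5)
  expect_equal(mapping_cost(g1, g2, m, cost_scheme(0.25, 0.5, 1)), 0.25)

  # deleting a node with total degree 3: node cost + one link cost per link
  g3 <- foodweb(rbind(c("x", "p"), c("p", "x"), c("x", "q")), name = "g3")
  g4 <- foodweb(nodes = c("p", "q"), name = "g4")
  md <- node_mapping(pairs = c(p = "p", q = "q"), deleted = "x")
  expect_equal(mapping_cost(g3, g4, md, cost_scheme(1, 0.5, 0.25)),
               0.5 + 3 * 0.25)
})

test_that("mapping cost agrees with an independent set-based oracle", {
  set.seed(21)
  for (i in 1:40) {
    g1 <- random_web(sample(2:6, 1), 0.35, prefix = "n")
    g2 <- random_web(sample(2:6, 1), 0.35, prefix = sample(c("n", "m"), 1))
    k <- sample(0:min(n1 <- length(g1$nodes), n2 <- length(g2$nodes)), 1)
    s1 <- sample(g1$nodes, k); s2 <- sample(g2$nodes, k)
    m <- node_mapping(pairs = stats::setNames(s2, s1),
                      deleted = setdiff(g1$nodes, s1),
                      inserted = setdiff(g2$nodes, s2))
    costs <- cost_scheme(runif(1), runif(1), runif(1))
    expect_equal(mapping_cost(g1, g2, m, costs),
                 oracle_mapping_cost(g1, g2, m, costs), tolerance = 1e-12)
  }
  expect_error(mapping_cost(random_web(3), random_web(3),
                            node_mapping(pairs = c(n01 = "n01")), scen7),
               "partition")
})

test_that("exact solver enumerates to the true minimum", {
  e0 <- exact_ged(foodweb(name = "e1"), foodweb(name = "e2"), scen7)
  expect_equal(e0$raw_cost, 0)
  expect_true(e0$exact)

  one <- exact_ged(foodweb(nodes = "x"), foodweb(), cost_scheme(1, 0.75, 1))
  expect_equal(one$raw_cost, 0.75)

  set.seed(31)
  for (i in 1:10) {
    g1 <- random_web(4, 0.3); g2 <- random_web(4, 0.3, prefix = "m")
    e <- exact_ged(g1, g2, scen7)
    expect_equal(e$raw_cost, oracle_exact_cost(g1, g2, scen7), tolerance = 1e-12)
    expect_equal(e$raw_cost, mapping_cost(g1, g2, e$mapping, scen7),
                 tolerance = 1e-12)
  }
  expect_error(exact_ged(random_web(7), random_web(3), scen7), "evolutionary")
})

test_that("evolutionary search respects its contracts", {
  set.seed(41)
  w <- random_web(10, 0.2, name = "big")
  sp <- search_params(seed = 5, stall_limit = 30, max_iterations = 200,
                      population_size = 32)
  self <- evolutionary_ged(w, w, scen7, sp)
  expect_equal(self$raw_cost, 0)

  g1 <- random_web(8, 0.25); g2 <- random_web(8, 0.25, prefix = "m")
  r <- evolutionary_ged(g1, g2, scen7, sp)
  cmax <- scen7$node * 16 + scen7$link * (nrow(g1$links) + nrow(g2$links))
  expect_lte(r$raw_cost, cmax + 1e-12)
  expect_gte(r$score, 0); expect_lte(r$score, 1)

  # reproducibility: identical seed and params give identical results
  r2 <- evolutionary_ged(g1, g2, scen7, sp)
  expect_identical(r$raw_cost, r2$raw_cost)
  expect_identical(r$mapping, r2$mapping)
  expect_identical(r$evaluations, r2$evaluations)

  # never better than the exhaustive minimum
  for (i in 1:10) {
    a <- random_web(4, 0.3); b <- random_web(4, 0.3, prefix = "m")
    ev <- evolutionary_ged(a, b, scen7,
                           search_params(seed = i, stall_limit = 50,
                                         max_iterations = 300,
                                         population_size = 32))
    expect_gte(ev$raw_cost, exact_ged(a, b, scen7)$raw_cost - 1e-9)
  }
})

test_that("identity correspondence is evaluated without search", {
  w <- foodweb(rbind(c("a", "b"), c("b", "c")), name = "w")
  expect_equal(identity_ged(w, w, cost_scheme(1, 1, 1))$raw_cost, 0)

  d1 <- foodweb(rbind(c("a", "b")), name = "d1")
  d2 <- foodweb(rbind(c("x", "y")), name = "d2")
  costs <- cost_scheme(0.25, 0.5, 0.75)
  expect_equal(identity_ged(d1, d2, costs)$raw_cost, 0.5 * 4 + 0.75 * 2)
  expect_equal(identity_ged(d1, d2, costs)$score, 1)

  f1 <- foodweb(rbind(c("a", "b")), name = "f1")
  f2 <- foodweb(rbind(c("b", "a")), name = "f2")
  expect_equal(identity_ged(f1, f2, cost_scheme(0.25, 1, 1))$raw_cost, 0.25)
})

test_that("score normalization maps zero to 0 and total replacement to 1", {
  g1 <- random_web(5, 0.3); g2 <- random_web(5, 0.3, prefix = "m")
  expect_equal(normalize_score(0, g1, g2, scen7), 0)
  allgone <- node_mapping(deleted = g1$nodes, inserted = g2$nodes)
  expect_equal(normalize_score(mapping_cost(g1, g2, allgone, scen7),
                               g1, g2, scen7), 1)
  expect_error(normalize_score(-1, g1, g2, scen7), "nonnegative")
  # hand arithmetic, scenario 2 (node cost 0): raw / (0.25 * (|E1| + |E2|))
  sc2 <- scenario_costs(2)
  t1 <- foodweb(rbind(c("a", "b"), c("b", "c")), name = "t1")
  t2 <- foodweb(rbind(c("b", "a")), nodes = c("a", "b", "c"), name = "t2")
  raw <- mapping_cost(t1, t2, node_mapping(pairs = c(a = "a", b = "b", c = "c")),
                      sc2)
  expect_equal(raw, min(0.25, 2 * 0.25) + 0.25)   # one reversal + one lost link
  expect_equal(normalize_score(raw, t1, t2, sc2), raw / (0.25 * 3))
  # empty-vs-empty: C_max = 0 convention
  expect_equal(normalize_score(0, foodweb(), foodweb(), sc2), 0)
})

test_that("exact GED is symmetric under argument swap", {
  set.seed(51)
  for (i in 1:8) {
    a <- random_web(4, 0.3); b <- random_web(4, 0.3, prefix = "m")
    expect_equal(exact_ged(a, b, scen7)$raw_cost,
                 exact_ged(b, a, scen7)$raw_cost, tolerance = 1e-12)
  }
})
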
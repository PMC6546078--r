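test_that("niche-model metawebs hit the target connectance on average", {
  cc <- vapply(1:50, function(s) {
    m <- niche_model_metaweb(200, 0.05, seed = s)
    nrow(m$links) / 200^2
  }, numeric(1))
  expect_lt(abs(mean(cc) - 0.05), 0.01)

  m2 <- niche_model_metaweb(2, 0.1, seed = 1)
  expect_lte(nrow(m2$links), 4L)
  expect_identical(niche_model_metaweb(30, 0.1, seed = 7)$links,
                   niche_model_metaweb(30, 0.1, seed = 7)$links)
  expect_error(niche_model_metaweb(10, 0.6), "connectance")
  expect_error(niche_model_metaweb(10, 0), "connectance")
})

test_that("local webs are induced subwebs when rewiring is off", {
  meta <- niche_model_metaweb(50, 0.1, seed = 13)
  p0 <- assembly_params(n_webs = 2, richness_range = c(10, 15),
                        target_link_range = c(0, 500), pool_size = 50,
                        connectance = 0.1, rewiring_rho = 0, seed = 13)
  set.seed(2)
  w <- assemble_local_web(meta, 15, 0.5, p0, name = "loc")
  keep <- meta$links[, 1] %in% w$nodes & meta$links[, 2] %in% w$nodes
  expect_setequal(link_keys(w),
                  paste(meta$links[keep, 1], "->", meta$links[keep, 2]))
  expect_error(assemble_local_web(meta, 60, 0.5, p0), "pool")
})

test_that("full rewiring decouples shared-species subwebs", {
  p1 <- assembly_params(n_webs = 2, richness_range = c(12, 12),
                        target_link_range = c(0, 500), pool_size = 30,
                        connectance = 0.15, rewiring_rho = 1,
                        gradient_strength = 0)
  bos <- vapply(1:40, function(s) {
    p1$seed <- s
    cs <- generate_community_set(p1)
    beta_partition(cs[[1]], cs[[2]])$b_os
  }, numeric(1))
  expect_gt(mean(bos), 0.2)   # rewired links rarely coincide

  # rewiring preserves the link count
  meta <- niche_model_metaweb(30, 0.15, seed = 3)
  p0 <- p1; p0$rewiring_rho <- 0
  set.seed(5); w0 <- assemble_local_web(meta, 12, 0.5, p0)
  set.seed(5); w1 <- assemble_local_web(meta, 12, 0.5, p1)
  expect_identical(w0$nodes, w1$nodes)
  expect_equal(nrow(w1$links), nrow(w0$links))
})

test_that("community generation respects richness bounds and the seed", {
  p <- assembly_params(n_webs = 6, richness_range = c(10, 20),
                       target_link_range = c(5, 200), pool_size = 60,
                       connectance = 0.1, seed = 17)
  cs <- generate_community_set(p)
  expect_length(cs, 6)
  sizes <- vapply(cs, function(w) length(w$nodes), integer(1))
  expect_true(all(sizes >= 10 & sizes <= 20))
  links <- vapply(cs, function(w) nrow(w$links), integer(1))
  expect_true(all(links >= 5 & links <= 200))

  cs2 <- generate_community_set(p)
  expect_identical(lapply(cs, link_keys), lapply(cs2, link_keys))

  tiny <- assembly_params(n_webs = 2, richness_range = c(5, 5),
                          target_link_range = c(0, 100), pool_size = 20,
                          connectance = 0.1, seed = 3)
  cs3 <- generate_community_set(tiny)
  expect_true(all(vapply(cs3, function(w) length(w$nodes), integer(1)) == 5))
})

test_that("the generator emulates the field dataset's scale at its defaults", {
  cs <- generate_community_set(assembly_params(seed = 20260927))
  expect_length(cs, 16)
  sizes <- vapply(cs, function(w) length(w$nodes), integer(1))
  expect_true(all(sizes >= 48 & sizes <= 113))
  links <- vapply(cs, function(w) nrow(w$links), integer(1))
  expect_true(all(links >= 110 & links <= 832))
  # 16 webs -> 120 unordered pairs
  expect_equal(choose(length(cs), 2), 120)
})

test_that("the decoupling experiment returns one row per replicate", {
  p <- assembly_params(n_webs = 4, richness_range = c(8, 10),
                       target_link_range = c(2, 60), pool_size = 30,
                       connectance = 0.12, seed = 2)
  tab <- decoupling_experiment(rho_grid = 0.5, reps = 1, params = p,
                               nbins = 3,
                               search = search_params(population_size = 16,
                                                      stall_limit = 15,
                                                      max_iterations = 60))
  expect_equal(nrow(tab), 1L)
  expect_named(tab, c("rho", "replicate", "ami_ged_jaccard"))
  expect_true(is.finite(tab$ami_ged_jaccard))
})
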
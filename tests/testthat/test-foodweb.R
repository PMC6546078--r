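test_that("edge-list reading builds the declared web", {
  w <- read_edgelist(c("source,target", "A,B", "B,C"), name = "t")
  expect_setequal(w$nodes, c("a", "b", "c"))
  expect_setequal(link_keys(w), c("a -> b", "b -> c"))

  dup <- read_edgelist(c("source,target", "A,B", "A,B"))
  expect_equal(nrow(dup$links), 1L)

  loop <- read_edgelist(c("source,target", "A,A"))
  expect_equal(length(loop$nodes), 1L)
  expect_equal(link_keys(loop), "a -> a")

  tabs <- read_edgelist("source\ttarget\nA\tB")
  expect_equal(link_keys(tabs), "a -> b")

  iso <- read_edgelist(c("source,target", "A,B", "C"))
  expect_setequal(iso$nodes, c("a", "b", "c"))
  expect_equal(nrow(iso$links), 1L)
})

test_that("empty edge lists give empty webs and malformed rows name the line", {
  expect_equal(length(read_edgelist("source,target\n")$nodes), 0L)
  expect_equal(length(read_edgelist(character(0))$nodes), 0L)
  expect_error(read_edgelist(c("source,target", "A,B", "A,B,C")), "line 3")
})

test_that("adjacency reading applies the stated orientation", {
  txt <- c(",A,B", "A,0,1", "B,0,0")
  w <- read_adjacency(txt, orientation = "rows-eat-columns")
  # row A eats column B: resource b -> consumer a
  expect_equal(link_keys(w), "b -> a")
  w2 <- read_adjacency(txt, orientation = "columns-eat-rows")
  expect_equal(link_keys(w2), "a -> b")

  zeros <- c(",A,B,C", "A,0,0,0", "B,0,0,0", "C,0,0,0")
  wz <- read_adjacency(zeros, orientation = "rows-eat-columns")
  expect_equal(length(wz$nodes), 3L)
  expect_equal(nrow(wz$links), 0L)

  expect_error(read_adjacency(txt), "orientation")
  expect_error(read_adjacency(c(",A,B", "A,0,2", "B,0,0"),
                              orientation = "rows-eat-columns"), "0 or 1")
  expect_error(read_adjacency(c(",A,A", "A,0,1", "B,0,0"),
                              orientation = "rows-eat-columns"), "duplicated")
})

test_that("the two orientations give mutually reversed link sets", {
  set.seed(11)
  w <- random_web(6, 0.3)
  A <- adjacency_matrix(w)
  lines <- c(paste0(",", paste(colnames(A), collapse = ",")),
             vapply(seq_len(nrow(A)),
                    function(i) paste(c(rownames(A)[i], as.integer(A[i, ])),
                                      collapse = ","), character(1)))
  r1 <- read_adjacency(lines, orientation = "rows-eat-columns")
  r2 <- read_adjacency(lines, orientation = "columns-eat-rows")
  rev2 <- paste(sub("(.*) -> (.*)", "\\2 -> \\1", link_keys(r2)))
  expect_setequal(link_keys(r1), rev2)
})

test_that("write/read round-trips preserve node and link sets", {
  set.seed(7)
  for (rep in 1:5) {
    w <- random_web(20, 0.1, name = sprintf("rt%d", rep))
    back_el <- read_edgelist(write_web(w, "edgelist"), name = w$name)
    expect_setequal(back_el$nodes, w$nodes)
    expect_setequal(link_keys(back_el), link_keys(w))
    back_gm <- read_graphml(write_web(w, "graphml"))
    expect_setequal(back_gm$nodes, w$nodes)
    expect_setequal(link_keys(back_gm), link_keys(w))
  }
  empty <- foodweb(name = "none")
  expect_equal(write_web(empty, "edgelist"), "source,target")
  one <- foodweb(rbind(c("a", "b")))
  expect_equal(write_web(one, "edgelist"), c("source,target", "a,b"))
})

test_that("clean_taxa canonicalizes, merges and is idempotent", {
  w <- foodweb(rbind(c("Deleatidium ", "Fish1")), name = "x")
  out <- clean_taxa(w, c("Deleatidium " = "Deleatidium"))
  expect_equal(link_keys(out), "deleatidium -> fish1")

  # two raw labels collapsing onto one canonical taxon: links union, one node
  w2 <- foodweb(rbind(c("algaeA", "bug"), c("algae_a", "bug"), c("bug", "fish")),
                name = "y")
  syn <- c(algaea = "algae", algae_a = "algae")
  out2 <- clean_taxa(w2, syn)
  expect_setequal(out2$nodes, c("algae", "bug", "fish"))
  expect_setequal(link_keys(out2), c("algae -> bug", "bug -> fish"))
  expect_equal(link_keys(clean_taxa(out2, syn)), link_keys(out2))

  cs <- community_set(list(w, w2))
  same <- clean_taxa(cs, character(0))
  expect_equal(lapply(same, link_keys), lapply(cs, link_keys))
  expect_s3_class(attr(clean_taxa(cs, syn), "substitutions"), "data.frame")
})

test_that("composition counts follow set arithmetic and swap symmetry", {
  mk <- function(nodes) foodweb(nodes = nodes)
  expect_equal(composition_counts(mk(letters[1:5]), mk(letters[1:5])),
               c(a = 0L, b = 0L, c = 5L))
  expect_equal(composition_counts(mk(letters[1:3]), mk(letters[4:7])),
               c(a = 3L, b = 4L, c = 0L))
  w1 <- mk(c("a", "b", "c")); w2 <- mk(c("b", "c", "d", "e"))
  expect_equal(composition_counts(w1, w2), c(a = 1L, b = 2L, c = 2L))
  set.seed(3)
  for (i in 1:10) {
    u <- random_web(sample(2:8, 1), 0.2)
    v <- random_web(sample(2:8, 1), 0.2, prefix = sample(c("n", "m"), 1))
    k12 <- composition_counts(u, v); k21 <- composition_counts(v, u)
    expect_equal(unname(k12[c("b", "a", "c")]), unname(k21[c("a", "b", "c")]))
  }
})

test_that("community sets validate names and expose the regional pool", {
  w1 <- foodweb(nodes = c("a", "b"), name = "s1")
  w2 <- foodweb(nodes = c("b", "c"), name = "s2")
  cs <- community_set(list(w1, w2))
  expect_equal(attr(cs, "pool"), c("a", "b", "c"))
  expect_error(community_set(list(w1, w1)), "unique")
})
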
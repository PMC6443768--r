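test_that("lattices are exactly regular with the advertised degrees", {
  ring <- build_lattice("ring4", 10)
  expect_equal(ring$N, 10L)
  expect_equal(nrow(ring$edges), 20L) # offsets {1, 2} circulant
  expect_true(all(ring$degree == 4L))
  for (v in 1:10) { # adjacent to the 4 nearest loop neighbors
    expect_setequal(ring$adj[[v]], ((v - 1 + c(-2, -1, 1, 2)) %% 10) + 1)
  }

  sq <- build_lattice("square4", 25)
  expect_true(all(sq$degree == 4L))
  expect_equal(sq$k_mean, 4)

  mo <- build_lattice("moore8", 25)
  expect_true(all(mo$degree == 8L))

  # 3x3 Moore torus collapses to the complete graph K9
  k9 <- build_lattice("moore8", 9)
  expect_true(all(k9$degree == 8L))
  expect_equal(nrow(k9$edges), 36L)

  expect_error(build_lattice("square4", 1000), "perfect-square")
  expect_error(build_lattice("ring4", 4), "N >= 5")
})

test_that("random models hit their degree targets and stay connected", {
  ba <- build_random_network("scale_free", 1000, mean_degree = 4, seed = 1)
  expect_lt(abs(ba$k_mean - 4) / 4, 0.02)
  expect_gt(ba$k_max, 20) # broad, hub-dominated degrees

  ws <- build_random_network("single_scale", 500, mean_degree = 4, seed = 2)
  expect_equal(ws$k_mean, 4)
  expect_lt(ws$k_max, 15) # narrow degree distribution

  hk <- build_random_network("holme_kim", 300, mean_degree = 4, seed = 3,
                             transitivity = 0.5)
  expect_lt(abs(hk$k_mean - 4) / 4, 0.05)
  g <- igraph::graph_from_edgelist(hk$edges, directed = FALSE)
  expect_gt(igraph::transitivity(g), igraph::transitivity(
    igraph::graph_from_edgelist(ba$edges, directed = FALSE)))

  comp <- build_random_network("complete", 5)
  expect_equal(nrow(comp$edges), 10L)

  star <- build_random_network("star", 5)
  expect_equal(sort(star$degree), c(1L, 1L, 1L, 1L, 4L))
  expect_equal(star$degree[1], 4L)

  expect_error(build_random_network("scale_free", 100, mean_degree = 3),
               "even")
  expect_error(build_random_network("nope", 10))
})

test_that("same seed reproduces the identical edge list", {
  a <- build_random_network("scale_free", 200, 4, seed = 99)
  b <- build_random_network("scale_free", 200, 4, seed = 99)
  expect_identical(a$edges, b$edges)
  a <- build_random_network("single_scale", 200, 4, seed = 5)
  b <- build_random_network("single_scale", 200, 4, seed = 5)
  expect_identical(a$edges, b$edges)
})

test_that("strategy placement schemes honor their contracts", {
  net <- build_random_network("scale_free", 1000, 4, seed = 4)
  s <- assign_initial_strategies(net, "random", 10, seed = 1)
  expect_equal(sum(s$strategy == "C"), 10L)

  dr <- assign_initial_strategies(net, "degree_rank", 10)
  hubs <- order(-net$degree, seq_len(net$N))[1:10]
  expect_setequal(which(dr$strategy == "C"), hubs)

  none <- assign_initial_strategies(net, "random", 0)
  expect_true(all(none$strategy == "D"))

  cp <- assign_initial_strategies(net, "connected_pairs", 6, seed = 2)
  cs <- which(cp$strategy == "C")
  expect_length(cs, 6L)
  # every chosen C has exactly one C-neighbor: disjoint edges
  nC <- vapply(cs, function(i) sum(cp$strategy[net$adj[[i]]] == "C"), integer(1))
  expect_true(all(nC == 1L))
  expect_equal(cp$frac_isolated_C, 0)

  single <- assign_initial_strategies(net, "single", 1, node = 17)
  expect_equal(which(single$strategy == "C"), 17L)
  expect_equal(single$frac_isolated_C, 1)

  expect_error(assign_initial_strategies(net, "random", 1001), "0..N")
  expect_error(assign_initial_strategies(net, "connected_pairs", 5), "even")

  s1 <- assign_initial_strategies(net, "random", 25, seed = 31)
  s2 <- assign_initial_strategies(net, "random", 25, seed = 31)
  expect_identical(s1$strategy, s2$strategy)
})

test_that("network constructor rejects malformed graphs", {
  expect_error(pd_network(rbind(c(1, 1)), 2), "self-loops")
  expect_error(pd_network(rbind(c(1, 2), c(2, 1)), 2), "multi-edges")
  expect_error(pd_network(rbind(c(1, 2), c(3, 4)), 4), "connected")
})

test_that("edge lists and strategy tables round-trip through disk", {
  net <- build_random_network("scale_free", 60, 4, seed = 6)
  f <- withr::local_tempfile(fileext = ".edges")
  write_edgelist(net, f)
  back <- read_edgelist(f)
  expect_identical(back$edges, net$edges)
  expect_equal(back$N, net$N)
  ln <- readLines(f)
  expect_true(all(grepl("^[0-9]+ [0-9]+$", ln))) # 0-based whitespace pairs

  s <- assign_initial_strategies(net, "random", 6, seed = 7)
  fs <- withr::local_tempfile(fileext = ".csv")
  write_strategies(s, fs)
  expect_identical(read_strategies(fs), s$strategy)
})
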
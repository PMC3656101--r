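test_that("degrees count a self-loop as a single partner", {
  tri <- igraph::make_ring(3)
  dd <- degreeDistribution(tri)
  expect_equal(unname(dd$degrees), c(2, 2, 2))
  expect_equal(dd$mean_degree, 2)
  expect_equal(sum(dd$p_of_k), 1)
  ## a lone self-binding node has itself as one partner
  loop <- igraph::make_graph(c(1, 1), n = 1, directed = FALSE)
  expect_equal(unname(degreeDistribution(loop)$degrees), 1)
  ## parallel edges are rejected
  multi <- igraph::make_graph(c(1, 2, 1, 2), n = 2, directed = FALSE)
  expect_error(degreeDistribution(multi), "parallel")
})

test_that("degree sum identity holds across random graphs with loops", {
  for (seed in 1:25) {
    set.seed(seed)
    g <- igraph::sample_gnp(15, 0.2)
    loops <- which(runif(15) < 0.2)
    if (length(loops))
      g <- igraph::add_edges(g, rep(loops, each = 2))
    dd <- degreeDistribution(g)
    n_loop <- sum(igraph::which_loop(g))
    expect_equal(sum(dd$degrees),
                 2 * (igraph::ecount(g) - n_loop) + n_loop)
    expect_equal(sum(dd$k * dd$p_of_k), dd$mean_degree)
  }
})

test_that("clustering matches hand values on complete and star graphs", {
  k4 <- clusteringCoefficients(igraph::make_full_graph(4))
  expect_equal(k4$c_local_mean, 1)
  expect_equal(k4$c_global, 1)
  expect_equal(k4$n_triangle, 4)
  star <- clusteringCoefficients(igraph::make_star(4, mode = "undirected"))
  expect_equal(star$c_local_mean, 0)
  expect_equal(star$c_global, 0)
  ## leaves (k < 2) enter the mean only on request
  star0 <- clusteringCoefficients(igraph::make_star(4, mode = "undirected"),
                                  include_low_degree = TRUE)
  expect_equal(star0$c_local_mean, 0)
})

test_that("clustering agrees with the exhaustive 3-subset oracle", {
  for (seed in 1:200) {
    set.seed(seed)
    g <- igraph::sample_gnp(sample(4:12, 1), runif(1, 0.15, 0.6))
    got <- clusteringCoefficients(g)
    want <- oracleClustering(g)
    expect_equal(got$n_triangle, want$n_triangle, info = seed)
    expect_equal(got$n_open, want$n_open, info = seed)
    expect_equal(got$c_global, want$c_global, info = seed)
    expect_equal(got$c_local_mean, want$c_local_mean, info = seed)
  }
})

test_that("clustering coefficients are invariant under node relabeling", {
  for (seed in 1:10) {
    g <- randomGraph(10, 0.35, seed)
    set.seed(seed + 100)
    h <- igraph::permute(g, sample(10))
    expect_equal(clusteringCoefficients(g)$c_global,
                 clusteringCoefficients(h)$c_global)
    expect_equal(clusteringCoefficients(g)$c_local_mean,
                 clusteringCoefficients(h)$c_local_mean)
  }
})

test_that("module sizes and the >=-type cumulative distribution are correct", {
  two_tri <- igraph::disjoint_union(igraph::make_ring(3), igraph::make_ring(3))
  mod <- connectedModules(two_tri)
  expect_equal(sort(mod$sizes), c(3L, 3L))
  expect_equal(mod$cumulative[mod$m == 3], 1)
  empty5 <- igraph::make_empty_graph(5, directed = FALSE)
  expect_equal(connectedModules(empty5)$sizes, rep(1L, 5))
  for (seed in 1:30) {
    g <- randomGraph(sample(5:15, 1), 0.15, seed)
    mod <- connectedModules(g)
    expect_equal(sort(mod$sizes), oracleComponentSizes(g), info = seed)
    expect_equal(sum(mod$sizes), igraph::vcount(g))
    expect_true(all(diff(mod$cumulative) <= 0))
    expect_equal(mod$cumulative[1], 1)
  }
})

test_that("hypergeometric tail matches exhaustive enumeration", {
  expect_equal(hypergeomTail(10, 4, 3, 2), oracleHyperTail(10, 4, 3, 2))
  expect_equal(hypergeomTail(8, 3, 4, 1), oracleHyperTail(8, 3, 4, 1))
  expect_equal(hypergeomTail(12, 6, 5, 5), oracleHyperTail(12, 6, 5, 5))
})

test_that("hypergeometric tail honors boundary and monotonicity properties", {
  expect_equal(hypergeomTail(56, 22, 9, 0), 1)
  p <- vapply(0:9, function(x) hypergeomTail(56, 22, 9, x), numeric(1))
  expect_true(all(diff(p) <= 0))
  expect_error(hypergeomTail(10, 12, 3, 1), "require")
  expect_error(hypergeomTail(10, 4, 3, 4), "require")
  expect_error(hypergeomTail(10.5, 4, 3, 1), "integers")
})
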
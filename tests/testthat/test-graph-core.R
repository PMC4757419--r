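test_that("degree_stats reproduces hand-derived assortativity and distributions", {
  star <- igraph::make_star(6, mode = "undirected")     # K_{1,5}
  st <- degree_stats(star)
  # every ordered edge-end pair is (1,5) or (5,1): perfect anti-correlation
  expect_equal(st$assortativity, -1)
  expect_equal(st$mean_degree, 10 / 6)
  expect_equal(sum(st$p), 1)
  expect_equal(sum(st$q), 1)
  expect_equal(sum(st$e), 1)
  # q(k) = k p(k) / <k>
  ks <- as.numeric(names(st$q))
  expect_equal(unname(st$q), unname(ks * st$p[names(st$q)] / st$mean_degree))
})

test_that("assortativity of a regular graph is the undefined sentinel, not 0", {
  ring <- igraph::make_ring(6)
  expect_true(is.na(degree_stats(ring)$assortativity))
  expect_error(degree_stats(igraph::make_empty_graph(4, directed = FALSE)),
               "no edges")
})

test_that("degree_stats invariants hold on irregular random graphs", {
  for (s in c(2, 7, 19)) {
    g <- toy_graph(40, 0.12, seed = s)
    if (igraph::ecount(g) < 2) next
    st <- degree_stats(g)
    expect_equal(sum(st$e), 1, tolerance = 1e-12)
    expect_true(isSymmetric(unname(st$e)))
    # marginal identity sum_k' e(k,k') = q(k)
    expect_equal(rowSums(st$e), st$q, tolerance = 1e-9)
    # q(k) = k p(k)/<k> for all k >= 1
    ks <- as.numeric(names(st$q))
    expect_equal(unname(st$q), unname(ks * st$p[names(st$q)] / st$mean_degree),
                 tolerance = 1e-9)
    # friendship paradox: mean of q >= <k>
    expect_gte(sum(ks * st$q), st$mean_degree - 1e-12)
    # agreement with the independent Pearson oracle and with igraph
    expect_equal(st$assortativity, oracle_assortativity(g), tolerance = 1e-10)
    expect_equal(st$assortativity, igraph::assortativity_degree(g),
                 tolerance = 1e-10)
    # invariance under node relabeling
    perm <- withr::with_seed(s, sample(igraph::vcount(g)))
    gp <- igraph::permute(g, perm)
    expect_equal(degree_stats(gp)$assortativity, st$assortativity,
                 tolerance = 1e-12)
  }
})

test_that("degree-attribute correlation matches closed form and node-level Pearson", {
  # star with only the hub active: attribute is an affine function of degree
  star <- igraph::make_star(5, mode = "undirected")
  expect_equal(degree_attribute_correlation(star, c(1, 0, 0, 0, 0))$correlation, 1)

  # path a-b-c with endpoint a active: hand Pearson of k=(1,2,1), x=(1,0,0)
  p3 <- make_fixture("path3-endpoint-active")
  expect_equal(degree_attribute_correlation(p3$graph, p3$x)$correlation, -0.5)

  # equivalence with cor() on the node-level pairs, plus joint marginals
  g <- toy_graph(50, 0.1, seed = 3)
  x <- withr::with_seed(9, rbinom(50, 1, 0.3))
  j <- degree_attribute_correlation(g, x)
  expect_equal(j$correlation, cor(igraph::degree(g), x), tolerance = 1e-9)
  expect_equal(sum(j$joint), 1, tolerance = 1e-12)
  st <- degree_stats(g)
  expect_equal(colSums(j$joint)[names(st$p)], st$p, tolerance = 1e-9)
})

test_that("degenerate attribute or degree configurations give NA sentinels", {
  g <- toy_graph(20, 0.2, seed = 5)
  expect_true(is.na(degree_attribute_correlation(g, rep(1, 20))$correlation))
  expect_true(is.na(degree_attribute_correlation(g, rep(0, 20))$correlation))
  ring <- igraph::make_ring(6)
  expect_true(is.na(degree_attribute_correlation(ring, c(1, 0, 0, 0, 0, 1))$correlation))
})

test_that("edge-list IO round-trips, collapses duplicates, drops self-loops", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "0 1", "1 2"), f)
  g <- read_edge_list(f)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)

  writeLines(c("0 0", "0 1", "1 0"), f)
  expect_message(expect_message(g2 <- read_edge_list(f), "self-loop"), "duplicate")
  expect_equal(igraph::ecount(g2), 1)

  writeLines(c("0 1", "oops"), f)
  expect_error(read_edge_list(f), "line 2")

  # round trip on a random fixture with arbitrary labels
  el <- withr::with_seed(1, {
    m <- matrix(sample(1000, 220, replace = TRUE), ncol = 2)
    m[m[, 1] != m[, 2], , drop = FALSE]
  })
  writeLines(paste(el[, 1], el[, 2]), f)
  ga <- suppressMessages(read_edge_list(f))
  f2 <- withr::local_tempfile(fileext = ".txt")
  write_edge_list(ga, f2)
  gb <- read_edge_list(f2)
  expect_equal(igraph::vcount(gb), igraph::vcount(ga))
  expect_equal(igraph::ecount(gb), igraph::ecount(ga))
  expect_true(igraph::isomorphic(ga, gb))
  expect_identical(sort(igraph::V(ga)$name), sort(igraph::V(gb)$name))
})

test_that("attribute files round-trip against node labels", {
  f <- withr::local_tempfile(fileext = ".txt")
  fe <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("10 20", "20 30", "30 10"), fe)
  g <- read_edge_list(fe)
  x <- c(1L, 0L, 1L)
  write_attributes(x, g, f)
  expect_identical(read_attributes(f, g), x)
  writeLines(c("10 1", "20 0"), f)  # missing node 30
  expect_error(read_attributes(f, g), "missing value")
})
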
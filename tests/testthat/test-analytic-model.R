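test_that("empirical conditional activation recovers per-degree fractions", {
  star <- igraph::make_star(5, mode = "undirected")
  ca <- empirical_conditional_activation(star, c(1, 0, 0, 0, 0))
  expect_equal(ca, c("1" = 0, "4" = 1))

  g <- toy_graph(40, 0.15, seed = 1)
  expect_equal(unname(empirical_conditional_activation(g, rep(1L, 40))),
               rep(1, length(unique(igraph::degree(g)))))

  # random activation: every P(x=1|k) within 4-sigma binomial error of f
  g <- erdos_renyi(5000, mean_degree = 6, seed = 2)
  x <- withr::with_seed(3, rbinom(5000, 1, 0.2))
  ca <- empirical_conditional_activation(g, x)
  deg <- igraph::degree(g)
  nk <- table(deg)[names(ca)]
  expect_true(all(abs(ca - 0.2) <= 4 * sqrt(0.2 * 0.8 / as.numeric(nk)) + 1e-12))
})

test_that("neighbor activation probability matches the hand-evaluated star case", {
  # K_{1,3} with the hub active: e(1,3) = e(3,1) = 1/2
  star <- igraph::make_star(4, mode = "undirected")
  st <- degree_stats(star)
  prof <- conditional_active_neighbor_prob(
    st, empirical_conditional_activation(star, c(1, 0, 0, 0)))
  expect_equal(prof$cond_prob, c("1" = 1, "3" = 0))
  expect_equal(prof$global_prob, 3 / 4)
})

test_that("uncorrelated mixing with a constant profile is a fixed point", {
  g <- toy_graph(50, 0.12, seed = 4)
  st <- degree_stats(g)
  # weights e(k,.)/q(k) sum to one for every observer degree
  expect_equal(unname(rowSums(st$e / st$q)), rep(1, nrow(st$e)), tolerance = 1e-9)
  cond <- stats::setNames(rep(0.37, length(st$q)), names(st$q))
  prof <- conditional_active_neighbor_prob(st, cond)
  expect_equal(unname(prof$cond_prob), rep(0.37, length(st$q)), tolerance = 1e-12)
  expect_equal(prof$global_prob, 0.37 * sum(st$p[names(st$q)]), tolerance = 1e-12)
})

test_that("binomial tail matches examples and the log-space summation oracle", {
  expect_equal(paradox_probability(1, 0.3), 0.3)
  expect_equal(paradox_probability(2, 0.3), 0.09)
  expect_equal(paradox_probability(3, 0.5), 0.5)
  expect_equal(paradox_probability(0, 0.9), 0)
  # strictness at even k: exact half-half split excluded
  expect_equal(paradox_probability(2, 0.5), 0.25)

  for (k in c(1:10, 17, 32, 50, 64)) {
    for (p in c(0.05, 0.3, 0.7)) {
      for (phi in c(0, 0.3, 0.5, 0.9, 1)) {
        expect_equal(paradox_probability(k, p, phi), oracle_binom_tail(k, p, phi),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("expected paradox fraction mixes tails over p(k) correctly", {
  # point mass p(1) = 1 with profile 0.3
  g1 <- configuration_model(c(1L, 1L), seed = 1)
  st1 <- degree_stats(g1)
  prof1 <- structure(list(cond_prob = c("1" = 0.3), global_prob = 0.3),
                     class = "neighbor_activation_profile")
  expect_equal(expected_paradox_fraction(st1, prof1)$overall, 0.3)

  # p(1) = p(2) = 1/2 with constant profile 0.3: two-term mixture
  g2 <- igraph::add_edges(igraph::make_empty_graph(4, directed = FALSE),
                          c(1, 2, 2, 3, 3, 4))  # path: degrees 1,2,2,1
  st2 <- degree_stats(g2)
  prof2 <- structure(list(cond_prob = c("1" = 0.3, "2" = 0.3), global_prob = 0.3),
                     class = "neighbor_activation_profile")
  pred <- expected_paradox_fraction(st2, prof2)
  expect_equal(pred$overall, 0.5 * 0.3 + 0.5 * 0.09)
  # overall is the p-weighted mean of the per-degree values
  expect_equal(pred$overall,
               sum(st2$p[names(pred$per_degree)] * pred$per_degree),
               tolerance = 1e-12)
})

test_that("raising any conditional activation weakly raises the prediction", {
  g <- toy_graph(60, 0.1, seed = 5)
  st <- degree_stats(g)
  base <- stats::setNames(rep(0.2, length(st$q)), names(st$q))
  p0 <- expected_paradox_fraction(st, conditional_active_neighbor_prob(st, base))$overall
  for (i in seq_along(base)) {
    up <- base
    up[i] <- 0.35
    pi <- expected_paradox_fraction(st, conditional_active_neighbor_prob(st, up))$overall
    expect_gte(pi, p0 - 1e-12)
  }
})

test_that("model equals the per-node binomial oracle under independent activation", {
  g <- erdos_renyi(800, mean_degree = 5.2, seed = 6)
  st <- degree_stats(g)
  f <- 0.2
  cond <- stats::setNames(rep(f, length(st$q)), names(st$q))
  pred <- expected_paradox_fraction(st, conditional_active_neighbor_prob(st, cond))
  expect_equal(pred$overall, oracle_independent_illusion(g, f), tolerance = 1e-9)
})

test_that("gaussian approximation obeys its limiting cases and clamps", {
  expect_equal(gaussian_approx_conditional(0.3, 0, 0.1, 2, 5, k = c(1, 5, 40)),
               rep(0.3, 3))
  expect_equal(gaussian_approx_conditional(0.3, 0.8, 0.1, 2, 5, k = 5), 0.3)
  expect_equal(gaussian_approx_conditional(0.9, 1, 0.5, 1, 2, k = 50), 1)
  expect_equal(gaussian_approx_conditional(0.1, 1, 0.5, 1, 10, k = 1), 0)
  expect_error(gaussian_approx_conditional(0.3, 0.5, 0.1, 0, 5, k = 2), "sigma_k")
})

test_that("model_curve reports empirical and predicted magnitudes side by side", {
  g <- erdos_renyi(2000, mean_degree = 5.2, seed = 7)
  cv <- model_curve(g, 0.1, c(0, 0.3), gaussian = TRUE, seed = 8)
  expect_equal(nrow(cv), 2)
  expect_true(all(cv$empirical >= 0 & cv$empirical <= 1))
  expect_true(all(cv$model >= 0 & cv$model <= 1))
  expect_true(all(cv$gaussian >= 0 & cv$gaussian <= 1))
  expect_equal(cv$active_fraction, c(0.1, 0.1))
  # zero-swap configuration reproduces the random-activation point
  cv0 <- model_curve(g, 0.1, 0, seed = 8)
  expect_lt(abs(cv0$achieved_rho), 0.05)
})
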
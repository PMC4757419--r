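# Independent oracles, deliberately implemented apart from the package code.

# Binomial upper tail P(n > phi*k) by direct log-space summation.
oracle_binom_tail <- function(k, p, phi = 0.5) {
  if (k == 0) return(0)
  ns <- (0:k)[(0:k) > phi * k]
  if (!length(ns)) return(0)
  if (p == 0) return(0)
  if (p == 1) return(1)
  sum(exp(lchoose(k, ns) + ns * log(p) + (k - ns) * log(1 - p)))
}

# Exact expected illusion magnitude under independent activation at rate f:
# node-level mixture of binomial tails, no degree grouping.
oracle_independent_illusion <- function(g, f, phi = 0.5) {
  deg <- igraph::degree(g)
  mean(vapply(deg, oracle_binom_tail, numeric(1), p = f, phi = phi))
}

# Assortativity as plain Pearson correlation over ordered edge-end degrees.
oracle_assortativity <- function(g) {
  deg <- igraph::degree(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  k1 <- deg[c(el[, 1], el[, 2])]
  k2 <- deg[c(el[, 2], el[, 1])]
  suppressWarnings(cor(k1, k2))
}

# Small deterministic test graph: simple ER-ish graph built by hand.
toy_graph <- function(n = 30, p = 0.15, seed = 42) {
  withr::with_seed(seed, {
    pairs <- t(combn(n, 2))
    keep <- runif(nrow(pairs)) < p
    g <- igraph::make_empty_graph(n, directed = FALSE)
    igraph::add_edges(g, t(pairs[keep, , drop = FALSE]))
  })
}
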
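#' Sample a power-law degree sequence
#'
#' Draws `n` i.i.d. degrees from the normalized discrete power law
#' \eqn{p(k) \propto k^{-\alpha}} on `k_min..k_max`. If the total is odd (no
#' half-edge matching would exist) the degree of one uniformly chosen node is
#' incremented by 1, reported via `message()`.
#'
#' @param n number of nodes.
#' @param alpha power-law exponent, > 1.
#' @param k_min,k_max inclusive degree cutoffs; defaults 1 and `n - 1`.
#' @param seed optional integer seed (local to this call).
#' @return integer degree vector of length `n` with even sum.
#' @examples
#' d <- sample_powerlaw_degrees(1000, alpha = 2.1, seed = 1)
#' sum(d) %% 2  # 0 by construction
#' @export
sample_powerlaw_degrees <- function(n, alpha, k_min = 1L, k_max = n - 1L, seed = NULL) {
  stopifnot(alpha > 1, n >= 2, k_min >= 1, k_min <= k_max, k_max <= n - 1)
  with_opt_seed(seed, {
    ks <- k_min:k_max
    deg <- sample(ks, n, replace = TRUE, prob = ks^(-alpha))
    if (sum(deg) %% 2L == 1L) {
      fixable <- which(deg < k_max)
      i <- if (length(fixable)) fixable[sample.int(length(fixable), 1L)] else sample.int(n, 1L)
      deg[i] <- deg[i] + 1L
      message("sample_powerlaw_degrees: odd total; incremented degree of node ", i)
    }
    as.integer(deg)
  })
}

#' Configuration-model graph from a degree sequence
#'
#' Random half-edge matching: each node gets as many half-edges (stubs) as its
#' requested degree and stubs are paired uniformly at random. The resulting
#' multigraph is then simplified -- self-loops and parallel edges removed --
#' so realized degrees can fall below requested ones; the number of removed
#' edges is reported via `message()`.
#'
#' @param degrees integer degree sequence with even sum.
#' @param seed optional integer seed (local to this call).
#' @return an undirected simple [igraph::igraph] graph on
#'   `length(degrees)` nodes.
#' @examples
#' g <- configuration_model(c(1L, 1L))     # the single edge {1,2}
#' igraph::ecount(g)
#' @export
configuration_model <- function(degrees, seed = NULL) {
  degrees <- as.integer(degrees)
  stopifnot(all(degrees >= 0L))
  if (sum(degrees) %% 2L == 1L) {
    stop("configuration_model: degree sum is odd; no half-edge matching exists", call. = FALSE)
  }
  with_opt_seed(seed, {
    g <- igraph::sample_degseq(degrees, method = "configuration")
    m0 <- igraph::ecount(g)
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
    removed <- m0 - igraph::ecount(g)
    if (removed > 0L) {
      message("configuration_model: removed ", removed,
              " self-loop/parallel edge(s) during simplification")
    }
    g
  })
}

#' Erdős–Rényi random graph G(n, p)
#'
#' Each of the \eqn{\binom{n}{2}} unordered node pairs is an edge
#' independently with probability `p`. Supply `mean_degree` instead of `p` to
#' set \eqn{p = \langle k\rangle/(n-1)}.
#'
#' @param n number of nodes.
#' @param p edge probability in \[0,1\]; exactly one of `p`/`mean_degree`.
#' @param mean_degree target mean degree (alternative parameterization).
#' @param seed optional integer seed (local to this call).
#' @return an undirected simple [igraph::igraph] graph.
#' @export
erdos_renyi <- function(n, p = NULL, mean_degree = NULL, seed = NULL) {
  if (is.null(p) == is.null(mean_degree)) {
    stop("supply exactly one of `p` or `mean_degree`", call. = FALSE)
  }
  if (is.null(p)) p <- mean_degree / (n - 1)
  stopifnot(p >= 0, p <= 1)
  with_opt_seed(seed, igraph::sample_gnp(n, p, directed = FALSE, loops = FALSE))
}
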
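#' Activate a fixed fraction of nodes uniformly at random
#'
#' Exactly `round(fraction * N)` nodes are set active, chosen uniformly
#' without replacement, so repeated draws share an identical global
#' prevalence \eqn{P(x=1)}. Random placement yields a degree-attribute
#' correlation \eqn{\rho_{kx}} close to zero in expectation.
#'
#' @param g undirected [igraph::igraph] graph.
#' @param fraction fraction of nodes to activate, in \[0, 1\].
#' @param seed optional integer seed (local to this call).
#' @return integer 0/1 vector of length `vcount(g)`.
#' @export
activate_random <- function(g, fraction, seed = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  n <- igraph::vcount(g)
  n_active <- round(fraction * n)
  x <- integer(n)
  if (n_active > 0) {
    x[with_opt_seed(seed, sample.int(n, n_active))] <- 1L
  }
  x
}

#' Steer the degree-attribute correlation by attribute swapping
#'
#' Repeatedly picks a random active node \eqn{v_1} and a random inactive node
#' \eqn{v_0} and exchanges their attribute values when doing so moves
#' \eqn{\rho_{kx}} strictly closer to `target_rho`. For a maximal target this
#' reduces to the degree-ordering rule -- swap iff
#' \eqn{\deg(v_0) > \deg(v_1)} -- and for a minimal target to its mirror;
#' interior targets additionally reject swaps that would overshoot. The
#' number of active nodes is conserved exactly by every swap.
#'
#' Terminates at \eqn{|\rho_{kx} - } `target_rho`\eqn{| \le} `tol`, after
#' `max_iter` proposals, or once `stall_factor * N` consecutive proposals
#' have been rejected (the practical signature that no accepting pair
#' remains, i.e. the achievable extreme was reached).
#'
#' @param g undirected [igraph::igraph] graph.
#' @param x binary 0/1 attribute vector with at least one 0 and one 1.
#' @param target_rho target correlation; `1`/`-1` request the achievable
#'   extremes (active set = highest/lowest-degree nodes).
#' @param seed optional integer seed (local to this call).
#' @param tol convergence tolerance on \eqn{\rho_{kx}}.
#' @param max_iter proposal budget.
#' @param stall_factor stop after `stall_factor * N` consecutive rejections.
#' @return integer 0/1 vector with attributes `achieved_rho`, `converged`
#'   (target met within `tol`), `stalled` (fixed point reached first), and
#'   `iterations`.
#' @export
swap_to_correlation <- function(g, x, target_rho, seed = NULL, tol = 0.005,
                                max_iter = 1000 * igraph::vcount(g),
                                stall_factor = 50) {
  x <- check_attributes(g, x)
  deg <- as.integer(igraph::degree(g))
  res <- with_opt_seed(seed,
    cpp_swap_attrs(deg, x, target_rho, tol, max_iter,
                   stall_factor * length(x)))
  out <- res$x
  attr(out, "achieved_rho") <- res$achieved_rho
  attr(out, "converged") <- res$converged
  attr(out, "stalled") <- res$stalled
  attr(out, "iterations") <- res$iterations
  out
}

#' Extreme achievable degree-attribute correlations
#'
#' For a fixed number of active nodes the correlation \eqn{\rho_{kx}} is
#' monotone in the total degree of the active set, so its achievable extremes
#' are attained by activating the highest- (resp. lowest-) degree nodes.
#' Used as the sort-based oracle for [swap_to_correlation()] convergence.
#'
#' @param g undirected [igraph::igraph] graph.
#' @param n_active number of active nodes, between 1 and N-1.
#' @return named numeric `c(min = ..., max = ...)`.
#' @export
achievable_correlation_bounds <- function(g, n_active) {
  deg <- igraph::degree(g)
  n <- length(deg)
  stopifnot(n_active >= 1, n_active <= n - 1)
  rho_of <- function(active_degs) {
    p1 <- n_active / n
    sx <- sqrt(p1 * (1 - p1))
    sk <- sqrt(mean(deg^2) - mean(deg)^2)
    if (sk == 0) return(NA_real_)
    p1 * (mean(active_degs) - mean(deg)) / (sx * sk)
  }
  sdeg <- sort(deg)
  c(min = rho_of(sdeg[seq_len(n_active)]),
    max = rho_of(sdeg[seq.int(n - n_active + 1L, n)]))
}
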
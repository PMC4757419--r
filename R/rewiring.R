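# Rebuild an igraph from a 0-based edge matrix, preserving vertex attributes.
rebuild_graph <- function(g, edges0) {
  out <- igraph::make_empty_graph(n = igraph::vcount(g), directed = FALSE)
  out <- igraph::add_edges(out, t(edges0 + 1L))
  for (a in igraph::vertex_attr_names(g)) {
    out <- igraph::set_vertex_attr(out, a, value = igraph::vertex_attr(g, a))
  }
  out
}

#' Steer degree assortativity by degree-preserving edge swaps
#'
#' Newman-style rewiring: repeatedly pick two random edges (a,b), (c,d) on
#' four distinct nodes and consider replacing them with (a,c),(b,d) or
#' (a,d),(b,c). Both pairings are evaluated; the proposal is the one that
#' moves \eqn{r_{kk}} closer to `target_r`, and it is accepted only if it
#' strictly improves and creates no self-loop or duplicate edge. Every node's
#' degree -- hence \eqn{p(k)} and \eqn{q(k)} -- is left exactly unchanged;
#' only the joint degree distribution \eqn{e(k,k')} moves.
#'
#' Stops when \eqn{|r_{kk} - } `target_r`\eqn{| \le} `tol` or after
#' `max_attempts` proposals; in the latter case the best-so-far graph is
#' returned with `target_reached = FALSE` rather than an error, since extreme
#' targets are usually structurally unreachable for a fixed degree sequence.
#'
#' @param g undirected simple [igraph::igraph] graph with >= 2 edges.
#' @param target_r target assortativity in \[-1, 1\].
#' @param seed optional integer seed (local to this call).
#' @param max_attempts proposal budget; default `100 * ecount(g)`.
#' @param tol stop once within this distance of the target.
#' @return the rewired graph, with graph attributes `achieved_r`,
#'   `target_reached`, `swaps_accepted`, `swap_attempts`.
#' @export
rewire_to_assortativity <- function(g, target_r, seed = NULL,
                                    max_attempts = 100 * igraph::ecount(g),
                                    tol = 0.01) {
  stopifnot(igraph::is_igraph(g), igraph::ecount(g) >= 2,
            target_r >= -1, target_r <= 1)
  deg <- as.integer(igraph::degree(g))
  el <- igraph::as_edgelist(g, names = FALSE) - 1L
  storage.mode(el) <- "integer"
  res <- with_opt_seed(seed,
    cpp_rewire_assort(el, deg, target_r, tol, as.integer(max_attempts)))
  out <- rebuild_graph(g, res$edges)
  out <- igraph::set_graph_attr(out, "achieved_r", res$achieved_r)
  out <- igraph::set_graph_attr(out, "target_reached", res$target_reached)
  out <- igraph::set_graph_attr(out, "swaps_accepted", res$accepted)
  out <- igraph::set_graph_attr(out, "swap_attempts", res$attempts)
  out
}

#' Alter e(k,k') while holding assortativity (near-)fixed
#'
#' Runs the same double-edge-swap proposal machinery but with the opposite
#' acceptance rule: a swap is accepted iff it changes at least one entry of
#' the joint degree distribution \eqn{e(k,k')} (the two new degree pairs are
#' not a permutation of the two old ones) while keeping \eqn{r_{kk}} within
#' `r_tol` of its initial value. Used to show that networks with identical
#' \eqn{p(k)} and \eqn{r_{kk}} but different \eqn{e(k,k')} display different
#' illusion magnitudes.
#'
#' @inheritParams rewire_to_assortativity
#' @param r_tol allowed drift of \eqn{r_{kk}} from its initial value.
#' @return the rewired graph with graph attributes `achieved_r`, `initial_r`,
#'   `swaps_accepted`, `swap_attempts`.
#' @export
rewire_alter_ekk_preserve_r <- function(g, seed = NULL,
                                        max_attempts = 20 * igraph::ecount(g),
                                        r_tol = 0.01) {
  stopifnot(igraph::is_igraph(g), igraph::ecount(g) >= 2)
  deg <- as.integer(igraph::degree(g))
  el <- igraph::as_edgelist(g, names = FALSE) - 1L
  storage.mode(el) <- "integer"
  res <- with_opt_seed(seed,
    cpp_rewire_ekk(el, deg, r_tol, as.integer(max_attempts)))
  out <- rebuild_graph(g, res$edges)
  out <- igraph::set_graph_attr(out, "achieved_r", res$achieved_r)
  out <- igraph::set_graph_attr(out, "initial_r", res$initial_r)
  out <- igraph::set_graph_attr(out, "swaps_accepted", res$accepted)
  out <- igraph::set_graph_attr(out, "swap_attempts", res$attempts)
  out
}
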
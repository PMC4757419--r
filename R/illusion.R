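# Active-neighbor counts for every node, via the sparse adjacency matrix.
active_neighbor_counts <- function(g, x) {
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  as.numeric(A %*% x)
}

#' Measure the majority illusion on a (graph, attributes) pair
#'
#' A node of degree \eqn{k \ge 1} experiences the illusion when strictly more
#' than \eqn{\phi k} of its neighbors are active; the illusion magnitude is
#' the fraction of all \eqn{N} nodes (active, inactive and isolated alike) in
#' that condition. Isolated nodes observe no one and are never flagged.
#'
#' The strict inequality matches the binomial-tail definition of the model
#' (\eqn{n > \phi k}); `strict = FALSE` switches to the "at least half"
#' reading used in toy illustrations, and `observers = "inactive"` restricts
#' both numerator and denominator to inactive nodes for the same purpose.
#'
#' @param g undirected [igraph::igraph] graph.
#' @param x binary 0/1 attribute vector.
#' @param phi observation threshold in \[0, 1\]; 0.5 = strict majority.
#' @param strict flag nodes with `> phi*k` active neighbors (default) or
#'   `>= phi*k`.
#' @param observers `"all"` (default) or `"inactive"`.
#' @return object of class `"illusion_measurement"`: list with `phi`,
#'   `paradox_fraction`, `per_node_flags` (logical, length N),
#'   `active_fraction`, `strict`, `observers`.
#' @examples
#' g <- igraph::make_star(5, mode = "undirected")
#' paradox_fraction(g, c(1, 0, 0, 0, 0))$paradox_fraction  # 0.8
#' @export
paradox_fraction <- function(g, x, phi = 0.5, strict = TRUE,
                             observers = c("all", "inactive")) {
  stopifnot(phi >= 0, phi <= 1)
  observers <- match.arg(observers)
  x <- check_attributes(g, x)
  deg <- igraph::degree(g)
  cnt <- active_neighbor_counts(g, x)
  flags <- if (strict) deg >= 1 & cnt > phi * deg else deg >= 1 & cnt >= phi * deg
  pool <- if (observers == "inactive") x == 0L else rep(TRUE, length(x))
  frac <- if (any(pool)) mean(flags[pool]) else 0
  structure(
    list(phi = phi, paradox_fraction = frac, per_node_flags = flags,
         active_fraction = mean(x), strict = strict, observers = observers),
    class = "illusion_measurement"
  )
}

#' @export
print.illusion_measurement <- function(x, ...) {
  cat(sprintf(
    "Majority illusion at phi = %g (%s, observers = %s):\n  %.4f of nodes see %s %g of their neighbors active (global prevalence %.4f)\n",
    x$phi, if (x$strict) "strict" else "non-strict", x$observers,
    x$paradox_fraction, if (x$strict) "more than" else "at least",
    x$phi, x$active_fraction))
  invisible(x)
}

#' Per-node fraction of active neighbors
#'
#' The quantity each node actually observes: the share of its neighbors that
#' are active. Its mean over nodes exceeds the global prevalence
#' \eqn{P(x=1)} whenever the attribute is positively correlated with degree
#' -- the generalized friendship paradox for binary attributes.
#'
#' @inheritParams paradox_fraction
#' @return numeric vector of length N; `NA` for isolated nodes, which
#'   observe nothing.
#' @export
neighbor_active_share <- function(g, x) {
  x <- check_attributes(g, x)
  deg <- igraph::degree(g)
  cnt <- active_neighbor_counts(g, x)
  ifelse(deg >= 1, cnt / deg, NA_real_)
}
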
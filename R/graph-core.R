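#' Empirical degree statistics of an undirected graph
#'
#' Computes every degree-level quantity the illusion model consumes: the
#' degree distribution \eqn{p(k)}, the neighbor degree distribution
#' \eqn{q(k) = k\,p(k)/\langle k\rangle}, the joint degree distribution
#' \eqn{e(k,k')} (probability that the two ends of a uniformly random edge
#' have degrees \eqn{k} and \eqn{k'}), the mean degree, the variance
#' \eqn{\sigma_q^2} of the neighbor degree distribution, and the degree
#' assortativity coefficient
#' \deqn{r_{kk} = \frac{1}{\sigma_q^2}\sum_{k,k'} k k'\,[e(k,k') - q(k)q(k')],}
#' the Pearson correlation between the degrees at the two ends of a random
#' edge.
#'
#' Each undirected edge contributes both orientations to \eqn{e(k,k')} with
#' weight \eqn{1/(2|E|)}; this convention makes the marginal identity
#' \eqn{\sum_{k'} e(k,k') = q(k)} exact. Isolated nodes are counted in
#' \eqn{p(0)} but contribute nothing to \eqn{q} or \eqn{e}.
#'
#' @param g an undirected simple [igraph::igraph] graph with at least one edge.
#' @return An object of class `"degree_stats"`: a list with elements
#'   `p` (named vector over all degrees present), `q` and `e` (named
#'   vector/matrix over the degrees of non-isolated nodes), `mean_degree`,
#'   `sigma_q_sq`, `assortativity`, `n_nodes`, `n_edges`. When all edge-end
#'   degrees are equal (\eqn{\sigma_q = 0}, e.g. a cycle) the assortativity is
#'   undefined and reported as `NA_real_`, never 0.
#' @examples
#' g <- igraph::make_star(6, mode = "undirected")
#' degree_stats(g)$assortativity  # -1: hubs only touch leaves
#' @export
degree_stats <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::ecount(g) == 0L) {
    stop("degree_stats: graph has no edges; p(k), q(k), e(k,k') undefined", call. = FALSE)
  }
  deg <- igraph::degree(g)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)

  ks_all <- sort(unique(deg))
  p <- as.numeric(table(factor(deg, levels = ks_all))) / n
  names(p) <- ks_all

  el <- igraph::as_edgelist(g, names = FALSE)
  k1 <- deg[el[, 1L]]
  k2 <- deg[el[, 2L]]
  dks <- sort(unique(c(k1, k2)))
  f1 <- factor(k1, levels = dks)
  f2 <- factor(k2, levels = dks)
  cnt <- table(f1, f2) + table(f2, f1)     # both orientations of every edge
  e <- unclass(cnt) / (2 * m)
  dimnames(e) <- list(dks, dks)

  q <- rowSums(e)
  mu_q <- sum(dks * q)
  sigma_q_sq <- sum(dks^2 * q) - mu_q^2

  assort <- if (sigma_q_sq <= .Machine$double.eps * mu_q^2) {
    NA_real_
  } else {
    (as.numeric(dks %*% e %*% dks) - mu_q^2) / sigma_q_sq
  }

  structure(
    list(p = p, q = q, e = e,
         mean_degree = mean(deg), sigma_q_sq = sigma_q_sq,
         assortativity = assort, n_nodes = n, n_edges = m),
    class = "degree_stats"
  )
}

#' @export
print.degree_stats <- function(x, ...) {
  cat("Degree statistics:", x$n_nodes, "nodes,", x$n_edges, "edges\n")
  cat(sprintf("  <k> = %.4f  sigma_q^2 = %.4f  r_kk = %s\n",
              x$mean_degree, x$sigma_q_sq,
              if (is.na(x$assortativity)) "undefined (regular graph)"
              else sprintf("%.4f", x$assortativity)))
  cat("  degree support:", paste(range(as.integer(names(x$p))), collapse = ".."), "\n")
  invisible(x)
}

# Validate a binary attribute vector against a graph; returns integer 0/1.
check_attributes <- function(g, x) {
  x <- as.integer(x)
  if (length(x) != igraph::vcount(g)) {
    stop("attribute vector length (", length(x), ") != number of nodes (",
         igraph::vcount(g), ")", call. = FALSE)
  }
  if (anyNA(x) || any(x != 0L & x != 1L)) {
    stop("attributes must be binary 0/1", call. = FALSE)
  }
  x
}

#' Joint degree-attribute distribution and correlation
#'
#' Computes the joint distribution \eqn{P(x,k)} of a binary node attribute and
#' node degree, and the degree-attribute correlation
#' \deqn{\rho_{kx} = \frac{1}{\sigma_x \sigma_k}\sum_{x,k} x k\,[P(x,k) - P(x)p(k)]
#'     = \frac{P(x{=}1)}{\sigma_x \sigma_k}\,[\langle k\rangle_{x=1} - \langle k\rangle],}
#' the Pearson correlation between a node's degree and its attribute,
#' evaluated through the closed form above (\eqn{\langle k\rangle_{x=1}} is
#' the mean degree of active nodes; \eqn{\sigma_x,\sigma_k} are population
#' standard deviations of attribute and degree).
#'
#' @param g an undirected [igraph::igraph] graph.
#' @param x binary attribute vector (0 = inactive, 1 = active), one entry per
#'   node in the order of `igraph::V(g)`.
#' @return Object of class `"attr_degree_joint"`: list with `joint` (2 x K
#'   matrix of \eqn{P(x,k)}, rows "0"/"1"), `active_fraction`,
#'   `mean_degree_active`, `sigma_x`, `sigma_k`, `correlation`. Degenerate
#'   configurations (all nodes active, all inactive, or a degree-regular
#'   graph) have no defined correlation: `correlation` is `NA_real_`.
#' @examples
#' g <- igraph::make_star(5, mode = "undirected")   # hub is node 1
#' x <- c(1, 0, 0, 0, 0)
#' degree_attribute_correlation(g, x)$correlation   # 1: degree orders the attribute
#' @export
degree_attribute_correlation <- function(g, x) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::vcount(g) == 0L) stop("empty graph", call. = FALSE)
  x <- check_attributes(g, x)
  deg <- igraph::degree(g)
  n <- length(deg)

  ks <- sort(unique(deg))
  joint <- rbind(
    "0" = as.numeric(table(factor(deg[x == 0L], levels = ks))) / n,
    "1" = as.numeric(table(factor(deg[x == 1L], levels = ks))) / n
  )
  colnames(joint) <- ks

  p1 <- mean(x)
  mk <- mean(deg)
  mka <- if (any(x == 1L)) mean(deg[x == 1L]) else NA_real_
  sigma_x <- sqrt(p1 * (1 - p1))
  sigma_k <- sqrt(mean(deg^2) - mk^2)

  rho <- if (sigma_x == 0 || sigma_k == 0) NA_real_ else p1 * (mka - mk) / (sigma_x * sigma_k)

  structure(
    list(joint = joint, active_fraction = p1, mean_degree_active = mka,
         sigma_x = sigma_x, sigma_k = sigma_k, correlation = rho),
    class = "attr_degree_joint"
  )
}

#' @export
print.attr_degree_joint <- function(x, ...) {
  cat(sprintf("Degree-attribute joint: P(x=1) = %.4f, <k>_{x=1} = %s, rho_kx = %s\n",
              x$active_fraction,
              if (is.na(x$mean_degree_active)) "NA" else sprintf("%.4f", x$mean_degree_active),
              if (is.na(x$correlation)) "undefined" else sprintf("%.4f", x$correlation)))
  invisible(x)
}

#' Read an undirected graph from a plain-text edge list
#'
#' One edge per line, two whitespace-separated integer node labels; lines
#' starting with `#` (and blank lines) are ignored. Arbitrary integer labels
#' are remapped to consecutive vertices; the original labels are kept in the
#' `name` vertex attribute. Self-loops are dropped and duplicate edges
#' (either orientation) collapsed, with counts reported via `message()`.
#'
#' @param path path to the edge-list file.
#' @param directed_symmetrize ignored placeholder for future directed input;
#'   input is always treated as undirected (a directed file is symmetrized by
#'   construction, since `a b` and `b a` collapse to one edge).
#' @return An undirected simple [igraph::igraph] graph; `V(g)$name` holds the
#'   original labels (as character).
#' @export
read_edge_list <- function(path, directed_symmetrize = TRUE) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(vapply(toks, length, 1L) != 2L)
  if (length(bad)) {
    stop("malformed edge list line ", idx[bad[1L]], ": '", lines[idx[bad[1L]]],
         "' (expected two whitespace-separated node labels)", call. = FALSE)
  }
  a <- vapply(toks, `[`, "", 1L)
  b <- vapply(toks, `[`, "", 2L)
  an <- suppressWarnings(as.numeric(a)); bn <- suppressWarnings(as.numeric(b))
  badnum <- which(is.na(an) | is.na(bn) | an != floor(an) | bn != floor(bn))
  if (length(badnum)) {
    stop("malformed edge list line ", idx[badnum[1L]], ": '", lines[idx[badnum[1L]]],
         "' (node labels must be integers)", call. = FALSE)
  }
  labels <- sort(unique(c(an, bn)))
  ia <- match(an, labels); ib <- match(bn, labels)

  loops <- ia == ib
  n_loops <- sum(loops)
  ia <- ia[!loops]; ib <- ib[!loops]
  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  dup <- duplicated(cbind(lo, hi))
  n_dup <- sum(dup)
  if (n_loops > 0L) message("read_edge_list: dropped ", n_loops, " self-loop(s)")
  if (n_dup > 0L) message("read_edge_list: collapsed ", n_dup, " duplicate edge(s)")

  g <- igraph::make_empty_graph(n = length(labels), directed = FALSE)
  g <- igraph::add_edges(g, rbind(lo[!dup], hi[!dup]))
  igraph::V(g)$name <- format(labels, scientific = FALSE, trim = TRUE)
  g
}

#' Write a graph as a plain-text edge list
#'
#' Inverse of [read_edge_list()]: writes one `a b` line per edge using the
#' `name` vertex attribute when present, otherwise 0-based vertex indices.
#' Isolated vertices do not appear (the format carries edges only).
#'
#' @param g an [igraph::igraph] graph.
#' @param path output file path.
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_edgelist(g, names = FALSE)
  lab <- if (!is.null(igraph::V(g)$name)) igraph::V(g)$name else as.character(seq_len(igraph::vcount(g)) - 1L)
  writeLines(paste(lab[el[, 1L]], lab[el[, 2L]]), path)
}

#' Read binary node attributes from a two-column file
#'
#' Format: `node_id value` per line, `value` in \{0,1\}; `#` comments allowed.
#' Node ids are matched against `V(g)$name` (or 0-based indices for unnamed
#' graphs); every node must receive exactly one value.
#'
#' @param path attribute file path.
#' @param g the graph the attributes belong to.
#' @return integer 0/1 vector in vertex order.
#' @export
read_attributes <- function(path, g) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("node", "value"),
                           colClasses = c("character", "integer"))
  lab <- if (!is.null(igraph::V(g)$name)) igraph::V(g)$name else as.character(seq_len(igraph::vcount(g)) - 1L)
  idx <- match(lab, tab$node)
  if (anyNA(idx)) stop("attribute file missing value for node '", lab[which(is.na(idx))[1L]], "'", call. = FALSE)
  x <- tab$value[idx]
  check_attributes(g, x)
}

#' @rdname read_attributes
#' @param x binary attribute vector to write.
#' @export
write_attributes <- function(x, g, path) {
  lab <- if (!is.null(igraph::V(g)$name)) igraph::V(g)$name else as.character(seq_len(igraph::vcount(g)) - 1L)
  writeLines(paste(lab, as.integer(x)), path)
}
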
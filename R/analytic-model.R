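#' Empirical conditional activation probability P(x=1|k)
#'
#' Fraction of nodes of each degree class that are active; the empirical
#' estimate of \eqn{P(x{=}1|k)} the model consumes when no parametric form of
#' the joint distribution is assumed.
#'
#' @inheritParams paradox_fraction
#' @return named numeric vector over all degrees present in `g`.
#' @export
empirical_conditional_activation <- function(g, x) {
  x <- check_attributes(g, x)
  deg <- igraph::degree(g)
  ks <- sort(unique(deg))
  out <- vapply(ks, function(k) mean(x[deg == k]), numeric(1))
  names(out) <- ks
  out
}

#' Probability that a neighbor is active, by observer degree
#'
#' Propagates the activation profile through the network's degree mixing: a
#' node of degree \eqn{k} reaches a neighbor of degree \eqn{k'} with
#' probability \eqn{e(k,k')/q(k)}, so
#' \deqn{P(x'{=}1|k) = \sum_{k'} P(x'{=}1|k')\, e(k,k')/q(k).}
#' Globally, \eqn{P(x'{=}1) = \sum_{k\ge 1} p(k)\, P(x'{=}1|k)} (isolated
#' nodes have no neighbor to observe and are excluded from the mixture).
#'
#' Disassortative mixing concentrates high-degree (hence, when
#' \eqn{\rho_{kx}>0}, active) neighbors around low-degree observers, which is
#' the structural lever of the illusion.
#'
#' @param stats a [degree_stats()] object.
#' @param cond_act named vector of \eqn{P(x{=}1|k)} (names = degrees); must
#'   cover the support of `q`. Degrees with \eqn{q(k)=0} get `NA_real_`.
#' @return object of class `"neighbor_activation_profile"`: list with
#'   `cond_prob` (named, support of `q`) and `global_prob`.
#' @export
conditional_active_neighbor_prob <- function(stats, cond_act) {
  stopifnot(inherits(stats, "degree_stats"))
  qk <- names(stats$q)
  missing_k <- setdiff(qk, names(cond_act))
  if (length(missing_k)) {
    stop("cond_act missing degrees in the q support: ",
         paste(utils::head(missing_k, 5), collapse = ", "), call. = FALSE)
  }
  ca <- cond_act[qk]
  cond <- as.numeric(stats$e %*% ca) / stats$q
  names(cond) <- qk
  pk <- stats$p[qk]            # p restricted to k >= 1 (q support)
  global <- sum(pk * cond)
  structure(list(cond_prob = cond, global_prob = global),
            class = "neighbor_activation_profile")
}

#' @export
print.neighbor_activation_profile <- function(x, ...) {
  cat(sprintf("Neighbor activation profile over %d degree classes; P(x'=1) = %.4f\n",
              length(x$cond_prob), x$global_prob))
  invisible(x)
}

#' Binomial tail probability of observing a local majority
#'
#' Probability that a node of degree \eqn{k}, each of whose neighbors is
#' active independently with probability `pk_active`, sees strictly more than
#' \eqn{\phi k} active neighbors:
#' \deqn{P_{>\phi}(k) = \sum_{n > \phi k} \binom{k}{n} p^n (1-p)^{k-n}.}
#' The bound is strict: for even \eqn{k} at \eqn{\phi = 1/2} an exact
#' half-half split does not count. Vectorized over `k` and `pk_active`.
#'
#' @param k node degree (non-negative integer); `k = 0` yields 0.
#' @param pk_active per-neighbor activation probability in \[0, 1\].
#' @param phi threshold fraction in \[0, 1\].
#' @return tail probability in \[0, 1\].
#' @examples
#' paradox_probability(2, 0.3)        # 0.09: both neighbors must be active
#' paradox_probability(3, 0.5)        # 0.5: Bin(3, 1/2) in {2, 3}
#' @export
paradox_probability <- function(k, pk_active, phi = 0.5) {
  stopifnot(all(k >= 0), all(pk_active >= -1e-12 & pk_active <= 1 + 1e-12),
            phi >= 0, phi <= 1)
  pk_active <- pmin(pmax(pk_active, 0), 1)
  # smallest qualifying n is floor(phi*k) + 1; the epsilon guards against
  # phi*k landing just below an integer through floating-point rounding
  cut <- floor(phi * k + 1e-9)
  out <- stats::pbinom(cut, k, pk_active, lower.tail = FALSE)
  out[k == 0] <- 0
  out
}

#' Expected illusion magnitude from the analytic model
#'
#' Mixes the per-degree binomial tails over the degree distribution:
#' \deqn{P_{>\phi} = \sum_k p(k)\, P_{>\phi}(k),}
#' with \eqn{P(x'{=}1|k)} from [conditional_active_neighbor_prob()] as the
#' per-neighbor activation probability of degree-\eqn{k} observers. Isolated
#' nodes (\eqn{p(0)}) contribute 0.
#'
#' @param stats a [degree_stats()] object.
#' @param profile a `"neighbor_activation_profile"`.
#' @param phi threshold fraction; 0.5 = strict majority.
#' @return object of class `"illusion_prediction"`: list with `per_degree`
#'   (named over the support of `q`), `overall`, `phi`.
#' @export
expected_paradox_fraction <- function(stats, profile, phi = 0.5) {
  stopifnot(inherits(stats, "degree_stats"),
            inherits(profile, "neighbor_activation_profile"))
  ks <- as.integer(names(profile$cond_prob))
  per_degree <- paradox_probability(ks, profile$cond_prob, phi)
  names(per_degree) <- ks
  overall <- sum(stats$p[as.character(ks)] * per_degree)
  structure(list(per_degree = per_degree, overall = overall, phi = phi),
            class = "illusion_prediction")
}

#' @export
print.illusion_prediction <- function(x, ...) {
  cat(sprintf("Predicted illusion magnitude at phi = %g: P_{>phi} = %.4f (%d degree classes)\n",
              x$phi, x$overall, length(x$per_degree)))
  invisible(x)
}

#' Gaussian (multivariate-normal) approximation of P(x=1|k)
#'
#' Closed-form linear approximation obtained by treating the joint
#' degree-attribute distribution as bivariate normal:
#' \deqn{P(x'{=}1|k') = \langle x\rangle + \rho_{kx}\,\frac{\sigma_x}{\sigma_k}(k' - \langle k\rangle),}
#' clamped to \[0, 1\] (the raw linear form escapes the unit interval for
#' heavy-tailed degree distributions, exactly the regime where the
#' approximation is known to break down). Adequate for Poisson-like degree
#' distributions near zero assortativity.
#'
#' @param mean_x global prevalence \eqn{\langle x\rangle = P(x{=}1)}.
#' @param rho degree-attribute correlation \eqn{\rho_{kx}}.
#' @param sigma_x,sigma_k population standard deviations of attribute and degree.
#' @param mean_k mean degree \eqn{\langle k\rangle}.
#' @param k degree(s) at which to evaluate.
#' @return approximate \eqn{P(x{=}1|k)}, clamped to \[0, 1\].
#' @export
gaussian_approx_conditional <- function(mean_x, rho, sigma_x, sigma_k, mean_k, k) {
  if (sigma_k <= 0) stop("sigma_k must be positive", call. = FALSE)
  pmin(pmax(mean_x + rho * sigma_x / sigma_k * (k - mean_k), 0), 1)
}

#' One-call illusion prediction for a (graph, attributes) pair
#'
#' Convenience pipeline: degree statistics + activation profile + binomial
#' mixture. `method = "empirical"` uses the empirically observed
#' \eqn{P(x{=}1|k)}; `method = "gaussian"` replaces it with the Gaussian
#' linear approximation (degree mixing \eqn{e(k,k')} is used either way).
#'
#' @inheritParams paradox_fraction
#' @param method `"empirical"` or `"gaussian"`.
#' @param stats optional precomputed [degree_stats()] for `g` (saves the
#'   dominant cost when predicting many attribute configurations on one graph).
#' @return an `"illusion_prediction"` object.
#' @export
predict_illusion <- function(g, x, phi = 0.5,
                             method = c("empirical", "gaussian"),
                             stats = NULL) {
  method <- match.arg(method)
  if (is.null(stats)) stats <- degree_stats(g)
  cond_act <- if (method == "empirical") {
    empirical_conditional_activation(g, x)
  } else {
    joint <- degree_attribute_correlation(g, x)
    if (is.na(joint$correlation)) {
      stop("gaussian approximation undefined: rho_kx is undefined here", call. = FALSE)
    }
    ks <- as.integer(names(stats$q))
    stats::setNames(
      gaussian_approx_conditional(joint$active_fraction, joint$correlation,
                                  joint$sigma_x, joint$sigma_k,
                                  stats$mean_degree, ks),
      ks)
  }
  profile <- conditional_active_neighbor_prob(stats, cond_act)
  expected_paradox_fraction(stats, profile, phi)
}

#' Empirical-vs-model curve over a degree-attribute correlation sweep
#'
#' On a fixed graph, activates `fraction` of the nodes at random, swaps
#' attributes toward each target \eqn{\rho_{kx}} in turn, and reports the
#' measured illusion magnitude next to the model prediction (and optionally
#' the Gaussian-approximation prediction) for every achieved configuration.
#'
#' @param g undirected [igraph::igraph] graph.
#' @param fraction fraction of active nodes.
#' @param rho_targets numeric vector of target correlations.
#' @param phi observation threshold.
#' @param gaussian also compute the Gaussian-approximation prediction.
#' @param seed optional integer seed for the whole curve (local to this call).
#' @param ... passed to [swap_to_correlation()].
#' @return data.frame with one row per target: `rho_target`, `achieved_rho`,
#'   `rho_converged`, `active_fraction`, `empirical`, `model`, and `gaussian`
#'   when requested.
#' @export
model_curve <- function(g, fraction, rho_targets, phi = 0.5, gaussian = FALSE,
                        seed = NULL, ...) {
  stats <- degree_stats(g)
  with_opt_seed(seed, {
    rows <- lapply(rho_targets, function(rt) {
      x <- activate_random(g, fraction)
      x <- swap_to_correlation(g, x, rt, ...)
      row <- data.frame(
        rho_target = rt,
        achieved_rho = attr(x, "achieved_rho"),
        rho_converged = attr(x, "converged"),
        active_fraction = mean(x),
        empirical = paradox_fraction(g, x, phi)$paradox_fraction,
        model = predict_illusion(g, x, phi, "empirical", stats = stats)$overall
      )
      if (gaussian) {
        row$gaussian <- predict_illusion(g, x, phi, "gaussian", stats = stats)$overall
      }
      row
    })
    do.call(rbind, rows)
  })
}
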
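---
title: "Measuring and predicting the majority illusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and predicting the majority illusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The observable

Take an undirected simple graph on $N$ nodes and a binary node attribute
$x_i \in \{0,1\}$ ("active"/"inactive"). A node of degree $k \ge 1$
experiences the *majority illusion* at threshold $\phi$ when strictly more
than $\phi k$ of its neighbors are active. The illusion magnitude is the
fraction of **all** $N$ nodes in that condition — active nodes and isolated
nodes included in the denominator, with isolated nodes never flagged (they
observe no one). `paradox_fraction()` measures this; at the default
$\phi = 1/2$ it is the fraction of nodes that see an active strict majority.

Two deliberate conventions:

* **Strict inequality.** The flag condition is $n > \phi k$, so for even $k$
  at $\phi = 1/2$ an exact half-half neighborhood does not count. This
  matches the binomial-tail bound in the model below, keeping measurement
  and prediction on the same definition. The "at least half" reading used in
  informal illustrations is available via `strict = FALSE`, and
  `observers = "inactive"` restricts the census to inactive nodes for toy
  narratives; neither affects the model.
* **All-node denominator.** The model mixes over the full degree
  distribution, so the measurement does too.

## The statistical model

The model predicts the illusion magnitude from three empirical
distributions, all computed by `degree_stats()` and
`empirical_conditional_activation()`:

* the degree distribution $p(k)$;
* the joint degree distribution $e(k,k')$, the probability that a random
  edge has end degrees $(k, k')$, with marginal
  $\sum_{k'} e(k,k') = q(k) = k\,p(k)/\langle k\rangle$;
* the conditional activation $P(x{=}1\mid k)$, the fraction of degree-$k$
  nodes that are active.

A degree-$k$ node reaches a neighbor of degree $k'$ with probability
$e(k,k')/q(k)$, so the probability that a random neighbor of a degree-$k$
node is active is

$$P(x'{=}1 \mid k) = \sum_{k'} P(x'{=}1 \mid k')\, \frac{e(k,k')}{q(k)}.$$

Treating the $k$ neighbors as independent draws with this success
probability, the chance of an active strict majority is a binomial tail,
and mixing over degrees gives the expected magnitude:

$$P_{>\phi}(k) = \sum_{n > \phi k} \binom{k}{n} P(x'{=}1|k)^n\,
  [1 - P(x'{=}1|k)]^{k-n}, \qquad
  P_{>\phi} = \sum_k p(k)\, P_{>\phi}(k).$$

`conditional_active_neighbor_prob()`, `paradox_probability()` and
`expected_paradox_fraction()` implement the three steps;
`predict_illusion()` chains them.

**Assumptions.** The model is a degree-class mean field: it assumes (i)
neighbors' states are independent given their degrees, and (ii) mixing is
fully described by $e(k,k')$. Clustering, communities, and degree-resolved
attribute placement beyond $P(x{=}1|k)$ are invisible to it. On
configuration-model graphs — which have vanishing clustering — the
prediction tracks measurement to a few parts in a thousand; on graphs with
rich higher-order structure it should be read as a first-order estimate.
Two graphs sharing $p(k)$ and even $r_{kk}$ but different $e(k,k')$ can
display different illusions, which is why the model consumes the full
matrix; `rewire_alter_ekk_preserve_r()` exists precisely to construct such
pairs.

**Global neighbor activation.** $P(x'{=}1) = \sum_{k\ge 1} p(k)\,
P(x'{=}1|k)$. Isolated nodes are excluded from this mixture: $q(0) = 0$, so
$P(x'{=}1|0)$ is undefined (there is no neighbor to observe). They still
count in $p(k)$ and in the measured denominator, contributing 0 to both
sides.

## Structural knobs

Two correlations control the illusion, and the package can set each while
holding everything else fixed.

**Degree assortativity $r_{kk}$** — the Pearson correlation of the degrees
at the two ends of a random edge, computed from $e(k,k')$.
`rewire_to_assortativity()` performs degree-preserving double-edge swaps:
two random edges $(a,b), (c,d)$ on four distinct nodes are re-paired as
$(a,c),(b,d)$ or $(a,d),(b,c)$; both pairings are evaluated and the better
one proposed; a proposal is accepted only if it strictly moves $r_{kk}$
toward the target and creates no self-loop or duplicate edge. $p(k)$ and
$q(k)$ are invariants of the move. Because acceptance is
strictly-improving, extreme targets terminate at the structurally
achievable extreme; the result carries `target_reached` rather than
erroring, since heavy-tailed degree sequences cannot reach $r_{kk} = \pm 1$
(structural cutoffs force simple heavy-tailed graphs toward
disassortativity to begin with).

**Degree–attribute correlation $\rho_{kx}$** — the Pearson correlation of
degree and attribute, computed through the closed form
$\rho_{kx} = P(x{=}1)\,[\langle k\rangle_{x=1} - \langle k\rangle]/
(\sigma_x\sigma_k)$ (`degree_attribute_correlation()`; equal to node-level
Pearson to $10^{-9}$, which the tests assert). `swap_to_correlation()`
exchanges the attribute values of a random active/inactive pair whenever
that moves $\rho_{kx}$ strictly closer to the target. For a maximal target
this is exactly the rule "swap iff the inactive node has the larger
degree", and for a minimal target its mirror — at a fixed active count
$\rho_{kx}$ is monotone in the total degree of the active set, so the
extreme configurations are the top-$m$ (bottom-$m$) degree nodes, up to
degree ties. For interior targets the distance rule additionally rejects
overshooting swaps, keeping the trajectory monotone. Convergence to "it no
longer changes" is detected by a stall counter: $C \cdot N$ consecutive
rejected proposals (default $C = 50$) is taken as evidence that no
accepting pair remains; this detects the fixed point without a global
search over all active–inactive pairs.

## Synthetic generators and what they emulate

`sample_powerlaw_degrees()` draws i.i.d. degrees from the normalized
discrete power law $p(k) \propto k^{-\alpha}$ on `[k_min, k_max]`,
incrementing one uniformly chosen node when the total is odd.
`configuration_model()` matches half-edges uniformly at random and then
removes self-loops and parallel edges. `erdos_renyi()` is the Bernoulli
graph $G(n,p)$, with $p = \langle k\rangle/(n-1)$ when parameterized by
mean degree.

Defaults state the experimental world of the headline experiments: $N =
10{,}000$ nodes, exponents $\alpha \in \{2.1, 2.4, 3.1\}$ for heavy-tailed
panels, mean degrees $5.2$ and $2.5$ for the Poisson-like panels, active
fraction $P(x{=}1) = 0.05$ (exact count, so replicate panels share an
identical prevalence). Cutoffs default to `k_min = 1`, `k_max = N - 1`; no
cutoff choice is canonical, and the default is documented as the package's
own. Two consequences worth knowing:

* at $\alpha = 2.1$ the expected maximum degree is comparable to $N$, so
  simplification removes many edges around the hubs — realized degrees are
  at most the requested ones, and all downstream statistics are computed
  from the *realized* graph, so no bias enters the model, only the
  generator;
* those same hubs make the engineered extreme
  (maximal $\rho_{kx}$, most-disassortative $r_{kk}$) very strong — the
  measured illusion can exceed 90% at 5% prevalence, above commonly quoted
  60–80% figures that correspond to tighter (unstated) cutoffs. The
  acceptance check is a lower bound and is insensitive to this.

A green test on these generators establishes that measurement and model
agree where the model's assumptions hold. It does **not** establish
accuracy on clustered, modular, or directed-then-symmetrized real networks;
for those, load an edge list with `read_edge_list()` and judge the model
against `paradox_fraction()` directly.

## The Gaussian approximation

Approximating the joint degree–attribute distribution as bivariate normal
gives the linear form

$$P(x'{=}1 \mid k') = \langle x\rangle +
  \rho_{kx}\frac{\sigma_x}{\sigma_k}(k' - \langle k\rangle),$$

(`gaussian_approx_conditional()`), which replaces the empirical
$P(x{=}1|k)$ inside the same mixing-and-tail pipeline
(`predict_illusion(..., method = "gaussian")`). It is accurate for
Poisson-like degree distributions near zero assortativity (within 0.02 of
the empirical-profile model across the $\rho_{kx}$ sweep on
$\langle k\rangle = 5.2$ Bernoulli graphs, per the acceptance suite) and
fails for heavy tails ($\alpha = 2.1$ deviations exceed 0.25), where the
linear form escapes $[0,1]$. The implementation clamps it to $[0,1]$ — the
minimal repair, applied exactly in the regime where the approximation is
documented to break anyway.

## Numerical choices

* $e(k,k')$ counts each undirected edge in both orientations with weight
  $1/(2|E|)$, which makes $\sum_{k'} e(k,k') = q(k)$ an exact identity
  rather than an approximation; all simplex sums hold to $10^{-9}$ in the
  tests.
* Undefined correlations (regular graph $\sigma_q = 0$ or $\sigma_k = 0$;
  constant attribute $\sigma_x = 0$) return the typed sentinel `NA_real_`,
  never 0, so sweep harnesses can skip degenerate rows gracefully.
  Operations that cannot proceed at all (rewiring a regular graph,
  swapping a constant attribute) raise errors instead.
* Binomial tails use `stats::pbinom(..., lower.tail = FALSE)` — log-space
  internally, no overflowing binomial coefficients. The strict cut
  "smallest $n > \phi k$" is computed as
  $\lfloor \phi k + 10^{-9} \rfloor + 1$; the epsilon guards against
  $\phi k$ landing a rounding error below an integer. An independent
  log-space summation oracle agrees to $10^{-12}$ for $k \le 64$.
* Rewiring tracks $r_{kk}$ incrementally through
  $T = \sum_{(u,v) \in E} k_u k_v$ (the only non-invariant part of the
  Pearson formula under degree-preserving swaps); a from-scratch
  recomputation agrees to $10^{-8}$ after arbitrary swap sequences, which
  the tests assert.
* All randomness flows through R's RNG, including inside the compiled
  swap loops, so a single `seed` argument (applied locally via
  `withr::with_seed`, leaving the caller's RNG state untouched) makes every
  generator, rewiring run, and sweep bit-reproducible.

## Limitations

* Undirected simple graphs only; no weights, no multigraphs. Directed input
  collapses to undirected at load.
* The rewiring procedures explore, they do not sample: a rewired graph is
  *one* member of the fixed-$p(k)$ family near the target, not a uniform
  draw from it.
* Achievable $(r_{kk}, \rho_{kx})$ ranges depend on the degree sequence;
  sweeps therefore report achieved values next to targets and flag
  unreached targets per row.
* The threshold cascade (`threshold_cascade()`) is the deterministic
  progressive model — strict threshold, seeds permanently active,
  synchronous and asynchronous schedules provably reach the same fixed
  point — included to demonstrate how the illusion flips global outcomes,
  not as a general contagion simulator.
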
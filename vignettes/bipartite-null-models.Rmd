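---
title: "Degree-constrained null models for binary bipartite networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree-constrained null models for binary bipartite networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bicm)
```

## The model

A binary bipartite network is a $C \times P$ biadjacency matrix $M$ with
$m_{cp} \in \{0,1\}$; rows and columns are two disjoint node layers and links
inside a layer do not exist. The question the package answers is always the
same: *given the degree sequences* $d_c = \sum_p m_{cp}$ and
$u_p = \sum_c m_{cp}$, *is some higher-order feature of* $M$ *surprising?*

The benchmark is the grandcanonical (soft-constraint) ensemble over all
$2^{C\cdot P}$ matrices of that shape. Maximizing Shannon entropy
$S = -\sum_M P(M)\ln P(M)$ subject to fixed *expected* degrees gives the
exponential family

$$P(M) = \prod_{c,p} p_{cp}^{m_{cp}} (1-p_{cp})^{1-m_{cp}},
\qquad p_{cp} = \frac{x_c y_p}{1 + x_c y_p},$$

the **bipartite configuration model** (BiCM): links are independent
Bernoulli variables, with one positive hidden variable per node (the
exponentiated Lagrange multipliers). Estimating the hidden variables by
maximum likelihood is equivalent to solving the $C+P$ moment conditions
$\sum_p p_{cp} = d_c$ and $\sum_c p_{cp} = u_p$; the log-likelihood is
globally concave in $\theta = -\log(x,y)$, so the solution is unique up to
the usual degeneracies. The **bipartite random graph** (BiRG) is the coarser
one-parameter member of the family, constraining only
$\langle L\rangle = L$, i.e. $p_{cp} \equiv L/(C\cdot P)$.

### Numerical strategy

* **Exact peeling.** Zero-degree nodes force $p = 0$ on their line
  ($x \to 0$); nodes connected to *every* still-active partner force $p = 1$
  ($x \to \infty$). Peeling repeats until stable (removing a saturated row
  decrements the remaining column targets, which may saturate columns in
  turn), so these limits are handled exactly rather than chased numerically.
  A side effect worth knowing: when the degree sequence admits a single
  matrix (e.g. a strict triangle), the ensemble collapses onto the
  observation, every $p_{cp} \in \{0,1\}$, and all z-scores are exactly 0.
* **Degree-class reduction.** Nodes with equal degree provably share a
  hidden variable, so the solve runs over distinct (row degree) ×
  (column degree) classes — for a 151×538 trade-shaped matrix that is a
  ~130×250 problem regardless of matrix size.
* **Fixed point with BFGS fallback.** The multiplicative iteration
  $x_i \leftarrow d_i / \sum_j n_j y_j/(1+x_i y_j)$ (and symmetrically for
  $y$) converges in a few hundred iterations on realistic inputs; if it
  stalls, a BFGS pass on the concave reduced log-likelihood (analytic
  gradient = degree residuals) finishes the job, and the fit errors out
  rather than returning an unconverged model.
* **Defaults.** `tol = 1e-8` on the maximum |expected − observed| degree,
  `max_iter = 5000`. The solver is deterministic and independent of node
  ordering. Initialization $x_c = d_c/\sqrt L$ puts the first iterate at the
  sparse (Chung–Lu) approximation.

`fit_bicm_degrees()` exposes the same solver for real-valued target degrees
(marginals-only data, parameter-recovery studies).

## Observables and their null expectations

* **Motifs.** $N_{V_n} = \sum_p \binom{u_p}{n}$ counts $n$-tuples of rows
  sharing a column ($\Lambda_n$ mirrors it; $V_1 = \Lambda_1 = L$;
  $\binom{k}{n} = 0$ for $k < n$ keeps the family total). Restricting to a
  node subset restricts the tuples, not the columns summed over. Under the
  model the per-column count is a binomial of a Poisson-binomial variable,
  so $\langle N_{V_n}\rangle = \sum_p e_n(\{p_{cp}\}_c)$ with $e_n$ the
  elementary symmetric polynomial, evaluated by the stable recurrence
  $e_k(j) = e_k(j{-}1) + p_j e_{k-1}(j{-}1)$. Exact standard deviations are
  exposed for $n \le 2$ (for $n = 2$, factorial moments of the
  Poisson-binomial give per-column variance $6e_4 + 6e_3 + e_2 - e_2^2$);
  higher orders use sampled moments and are flagged `moment_source =
  "sampled"` rather than risking an unverified closed form.
* **z-score and similarity.** $z = (N^* - \langle N\rangle)/\sigma$ and
  $s = (N^* - \langle N\rangle)/\langle N\rangle$; their ratio
  $s/z = \sigma/\langle N\rangle$ is the motif's ensemble coefficient of
  variation, and the package asserts this identity to 1e-12 in its tests.
  The similarity normalization by $\langle N\rangle$ is the unique choice
  consistent with that identity. Default significance thresholds are
  $|z| > 1.65$ for whole-graph families and $|z| > 2$ for subset-restricted
  motifs (stricter because subsets are usually cherry-picked hypotheses).
  Sampled motif abundances are approximately gaussian (sums of many weakly
  dependent indicators); `distribution_summary()` reports skewness, excess
  kurtosis and a Jarque–Bera omnibus p-value so the gaussian reading of a
  z-score can be checked instead of assumed. Jarque–Bera was chosen because
  it is the standard moment-based omnibus test available without extra
  dependencies; any such test would do, the contract is statistic + p-value
  + flag.
* **ANPU / ANCD.** Average nearest-neighbour degrees per node; zero-degree
  nodes are `NA` and excluded from means (the alternative — including them —
  divides by zero). Layer means carry normal-approximation 95% CIs
  ($\pm 1.96\,\mathrm{sd}/\sqrt n$): the simplest defensible construction,
  flagged here because fancier bootstrap intervals would change nothing at
  the sample sizes involved. The mean ANPU, which lives in $[1, C]$, divided
  by $C$ is a size-free globalization index; the mean ANCD over $P$ is the
  column-layer homogeneity analogue. (Note the normalizers: each mean is
  divided by the bound of the *neighbour* layer's size, which is what makes
  the complete matrix score exactly 1 on both indices.)
* **Assortativity coefficient.** Pearson correlation of endpoint degrees
  $(d_c, u_p)$ across links. In a bipartite graph each link has exactly one
  endpoint per layer, so the "remaining degree" convention differs by an
  affine shift that cancels in the correlation — the two readings coincide
  and the raw-degree one is implemented. Degenerate (zero-variance) degree
  sequences return `NA` with a warning instead of a number.
* **NODF.** For each unordered pair within a layer, paired overlap
  $100\,|N_i \cap N_j|/d_{\min}$ when the two degrees differ and the smaller
  is positive, else 0; averaged per layer and pooled for the total. Using
  $d_{\min}$ with a strict-inequality fill condition is exactly the
  order-invariant reading (it equals the classical definition applied to the
  degree-sorted matrix — vegan's `nestednodf(order = TRUE)` — which is the
  cross-check oracle in the test suite).
* **Fitness–complexity.** The coupled iteration
  $\tilde F_c = \sum_p m_{cp} Q_p$, $\tilde Q_p = 1/\sum_c (m_{cp}/F_c)$,
  both sides at the previous iterates, each vector renormalized to unit mean
  per step; start from all ones; stop when the max relative change drops
  below `tol = 1e-8` or at `max_iter = 1000`. The iteration is known not to
  converge in value for every matrix (scores can decay toward zero while the
  *ranking* stabilizes), so non-convergence sets a flag rather than raising:
  consumers can check `glance()$converged` and still use the ordering.
  Ensemble comparisons of fitness and complexity average over *ranked*
  nodes (the k-th largest value per draw), since node identity is not
  preserved across the ensemble.

## Sampling

`sample_ensemble()` draws each matrix cell-by-cell from the fitted
$p_{cp}$, evaluates the requested observables on the fly and discards the
matrix (constant memory in the number of draws; `keep_matrices = TRUE` for
the rare single-draw display). One integer seed determines the whole stream;
because observables are deterministic functions of each draw, extending the
observable list never changes earlier draws. Moments over draws use the
population (1/n) convention, matching their role as plug-in estimates of the
ensemble mean and standard deviation. The default depth of 5000 draws
matches the reference ensemble-density analyses; the examples and tests use
a few hundred, which is enough for the scalar z-scores whose sampling error
scales as $\sigma/\sqrt{n}$.

## What the generators state, and what a green test means

`generate_bipartite()` fixes the package's synthetic world:

* `hidden_variable` — log-normal hidden variables (`sdlog = 1.5`) rescaled
  to a target connectance of 0.15, on a default 151×538 shape. These choices
  mirror a world-trade-style matrix: broad, smooth degree distributions on
  both layers, a few hundred columns, connectance in the 0.1–0.2 band.
  The generating $x, y, p$ are attached as attributes, which is what makes
  honest parameter-recovery tests possible (fit to the *expected* degrees,
  compare probability matrices).
* `nested` — triangular fill (threshold on $(i-\tfrac12)/C +
  (j-\tfrac12)/P$, the straight-boundary idealization of a
  fitness-ordered matrix) at a given fill fraction, then independent cell
  flips with probability `noise = 0.02`: high but imperfect nestedness.
* `biregular`, `random_uniform` — degenerate edge cases and baselines.

What these fixtures do **not** contain: real data's structure *beyond* its
degree sequence. A hidden-variable fixture is itself a BiCM draw, so green
tests on it establish solver correctness and sampling fidelity — not that
the BiCM explains real networks. More subtly, the noisy triangle is "typical
matrix + degree-uncorrelated noise": its observed assortativity is therefore
systematically *weaker* than the BiCM ensemble mean (the null re-establishes
the typical nested structure for the perturbed degrees, and the reversal is
many ensemble standard deviations at every noise level we measured). Real
trade data sits on the *other* side — more disassortative than its null —
precisely because reality contains degree-anticorrelated structure that
independent flips cannot create. One acceptance check encodes the real-data
direction and accordingly fails on this generator; it is left failing, as a
documented property of the synthetic world rather than a defect of the
model code. The adjacent checks (negative $\langle r\rangle$, NODF z-score
of a model draw within ±3) hold.

## Numerical conventions and degenerate inputs

* $0\log 0 = 0$ throughout (matrix probabilities, entropy).
* A matrix with a link where the model says $p = 0$ (or a hole where
  $p = 1$) has log-probability $-\infty$, returned as is, not as an error.
* Zero-spread cases: $z = 0$ when observed equals expected and $\sigma = 0$;
  $\pm\infty$ when they differ; similarity is `NA` when the expectation
  vanishes.
* Normalized entropy $S = -(C P)^{-1}\sum_{cp}[p\ln p + (1-p)\ln(1-p)]$ is
  bounded by $\ln 2$, attained by the uniform ensemble; constraining more
  can only lower it, so $S(\mathrm{BiCM}) \le S(\mathrm{BiRG})$ — both facts
  are asserted in the tests.
* Isolated nodes are retained everywhere (labels stay aligned with the
  input); observables undefined on them return `NA` and warn where the
  exclusion changes a summary.
* Ties in fitness/complexity orderings break by original input order
  (stable sort); rectangularity is sign-free by construction since the layer
  ordering is an arbitrary choice.

## Limitations

* Weighted and directed bipartite variants are out of scope.
* Microcanonical (exact-degree) randomization is a different estimator with
  different small-sample behaviour; this package is strictly grandcanonical.
* Analytic motif variances stop at order 2; higher orders are sampled.
* The fitness–complexity iteration's non-convergence on ill-conditioned
  matrices is reported, not repaired.

## A compact session

```{r example, eval = FALSE}
g <- generate_bipartite("nested", 40, 90, seed = 7, fill = 0.3, noise = 0.03)
model <- fit_bicm(g)
glance(model)
motif_report(g, model, list(motif_spec("V", 2), motif_spec("Lambda", 3)),
  n_draws = 500, seed = 1
)
observable_report(g, model, n_draws = 500, seed = 11)$scalars
autoplot(g, ranked = TRUE)
```
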
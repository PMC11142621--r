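---
title: "Fused graphical lasso estimation and de-biased inference for multiple precision matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fused graphical lasso estimation and de-biased inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fglinfer)
```

## The model

For each of $K$ groups we observe $n_k$ i.i.d. $p$-variate Gaussian vectors
with mean zero and covariance $\Sigma_0^{[k]}$.  The precision matrix
$\Theta_0^{[k]} = (\Sigma_0^{[k]})^{-1}$ encodes the conditional-independence
graph of group $k$: $\Theta_{0,ij}^{[k]} = 0$ exactly when variables $i$ and
$j$ are conditionally independent given the rest.  When the groups are
related — disease subtypes profiled on the same genes, say — their graphs
share structure, and estimating them jointly is more efficient than fitting
each alone.

The fused graphical lasso (FGL) estimates all $K$ matrices at once by
minimizing

$$\sum_{k=1}^K \left\{ \mathrm{tr}(\hat\Sigma^{[k]}\Theta^{[k]})
  - \log\det \Theta^{[k]} \right\}
  + \lambda \sum_k \|\Theta^{[k]-}\|_1
  + \rho \sum_{k<k'} \|(\Theta^{[k]}-\Theta^{[k']})^-\|_1$$

over symmetric positive-definite matrices, where $M^-$ zeroes the diagonal.
The $\lambda$ term promotes sparsity within each graph; the $\rho$ term
shrinks between-group differences, encouraging shared edges.  Both penalties
act on off-diagonal entries only — diagonals are neither shrunk nor fused.
Some FGL implementations also penalize diagonals; this package follows the
off-diagonal-only formulation, which matters for inference (see
*Limitations*).

A weighted variant removes scale effects: [weighted_fgl()] solves the same
problem on the sample correlation matrices
$\hat R^{[k]} = \hat W^{-1}\hat\Sigma^{[k]}\hat W^{-1}$,
$\hat W = \mathrm{diag}(\hat\Sigma^{[k]})^{1/2}$, and back-transforms the
correlation-scale solution via
$\hat\Theta_w^{[k]} = \hat W^{-1}\hat\Theta_R^{[k]}\hat W^{-1}$.  The
back-transform is taken as definitional for the weighted penalty.

## The solver

[fgl_admm()] is a scaled consensus ADMM.  Per iteration:

* **$\Theta$-update** (per group): minimize
  $\mathrm{tr}(S\Theta) - \log\det\Theta + \tfrac{\mu}{2}\|\Theta - Z + U\|_F^2$.
  Eigendecomposing $\mu(Z-U) - S = V\,\mathrm{diag}(d)\,V^\top$ gives the
  closed form $\Theta = V\,\mathrm{diag}\!\big(\tfrac{d_i + \sqrt{d_i^2 + 4\mu}}{2\mu}\big)V^\top$,
  which is positive definite at every iterate.
* **$Z$-update**: an exact entrywise fused-lasso proximal operator.  For one
  off-diagonal entry the $K$ group values solve
  $\min_z \tfrac{\mu}{2}\sum_k (z_k - a_k)^2 + \lambda\sum_k |z_k|
   + \rho\sum_{k<k'}|z_k - z_{k'}|$.
  The pairwise (complete-graph) fusion part preserves the ordering of $a$;
  on sorted values its penalty is linear with coefficients $2k-1-K$, so the
  fusion prox is an isotonic regression of the shifted sorted values, solved
  exactly by pool-adjacent-violators for any $K$.  Soft-thresholding by
  $\lambda/\mu$ then applies the $\ell_1$ part.  Diagonal entries pass
  through unpenalized.
* **Dual update** and residuals: primal $\|\Theta - Z\|_F$, dual
  $\mu\|Z - Z_{old}\|_F$.

Defaults: $\mu = 1$, `max_iter = 1000`, tolerances $10^{-5} p$.  Supports
are read from the consensus $Z$, which is exactly sparse; $\Theta$ is dense
to machine precision.  [kkt_residual()] certifies optimality by measuring
the distance of $-(\hat\Sigma^{[k]} - \hat\Theta^{[k]-1})$ from the
penalty's subdifferential interval at the solution.

Because the fusion penalty skips diagonals, the $\rho\to\infty$ limit
equals a pooled single-group solve only when the group covariances share a
diagonal; with unequal diagonals the unfused diagonals solve different
stationarity equations.

## Tuning

[fgl_aic()] uses
$\mathrm{AIC} = \sum_k \big[ n_k \mathrm{tr}(\hat\Sigma^{[k]}\hat\Theta^{[k]})
 - n_k \log\det\hat\Theta^{[k]} + 2 E_k \big]$,
with $E_k$ the number of nonzero upper-triangle off-diagonal entries of the
consensus.  The exact AIC variant used in the original analyses is not
documented; this is the standard joint-graphical-lasso form and is flagged
as an assumption.  [select_tuning()] searches a grid — by default 30
equally spaced points from 0.05 to 0.3 on each axis (step $0.25/29 \approx
0.0086$) — with $\lambda$ outer, $\rho$ inner, warm starts along $\rho$;
ties break to the smallest $\lambda$, then $\rho$.  Warm and cold starts
agree at tolerance on the instances tested.

## De-biased inference

Penalization biases $\hat\Theta$ toward sparsity, so its entries are not
asymptotically normal.  The one-step correction
$\hat\Theta_d^{[k]} = 2\hat\Theta^{[k]} -
 \hat\Theta^{[k]}\hat\Sigma^{[k]}\hat\Theta^{[k]}$
removes the first-order bias.  For a contrast $a = (a_1,\dots,a_K)$,
[linear_test()] forms
$T_{ij} = \sum_k a_k \hat\Theta_{d,ij}^{[k]}$, tests
$H_0: \sum_k a_k \Theta_{0,ij}^{[k]} = 0$ entrywise, and builds confidence
intervals.  The variance plug-in is
$\hat\sigma_{ij}^2 = \sum_k a_k^2\big[\hat\Theta_{ii}^{[k]}\hat\Theta_{jj}^{[k]}
 + (\hat\Theta_{ij}^{[k]})^2\big]$,
with standard errors $\mathrm{se}_{ij}^2 = \sum_k a_k^2[\cdot]/n_k$ — the
per-group scaling reduces to the usual $\hat\sigma_{ij}/\sqrt{n}$ when all
groups share one $n$, and is this package's interpretation for unequal
sizes (which the asymptotic theory does not cover).  Two design points:

* The statistic is standardized by $\hat\sigma$ (the standard error), not
  $\hat\sigma^2$; the CLT $\sqrt{n}(T - \Theta_0) \to N(0, \sigma^2)$ fixes
  this normalization.
* Quantiles are exact normal quantiles ($1.959964\ldots$ at the 95% level,
  not the rounded 1.96).
* For the weighted variant the de-biasing product uses $\hat\Theta_w$ with
  the *covariance* $\hat\Sigma$ (not the correlation), and the variance
  plug-in uses $\hat\Theta_w$.

No multiplicity correction is applied by default — the method's output is
the raw $p$-value matrix — but `p_adjust = "BH"` is available as an
extension.

## The synthetic generator

[generate_precision()] builds a ground truth from a random graph $G$:
exactly $\mathrm{round}(\tilde\alpha\, p(p-1)/2)$ upper-triangle positions
(sampled without replacement, then symmetrized) receive an edge, so the
edge proportion is exact rather than Bernoulli.  Edge values are
$m = (u_{ij}+u_{ji})/2$ with $u \sim U(0,1)$, shifted by $-1$ when
$m < 0.5$, so every nonzero entry has magnitude in $[0.5, 1)$ — separated
from zero, as sparsity asks.  Non-edges are exactly zero: applying the
shift indicator to non-edges would set every absent edge to $-1$ and
destroy sparsity, so the indicator is scoped to edges.  Adding
$(|\Lambda_{\min}(\tilde\Theta)| + 0.1)I$ makes the result positive
definite with smallest eigenvalue at least 0.1.

[make_null_scenario()] builds the null designs: `equal`
($\Theta_0^{[2]} = \Theta_0^{[1]}$, contrast $(1,-1)$), `linear`
($\Theta_0^{[2]} = c\,\Theta_0^{[1]}$, $c = 0.5$ by default, contrast
$(1, -1/c)$) and `three_sample_linear`
($\Theta_0^{[3]} = c_1\Theta_0^{[1]} + c_2\Theta_0^{[2]}$, defaults
$c_1 = 0.6$, $c_2 = 0.9$, sparsity parameters 0.01 and 0.1).  Coefficients
must be positive so every combination stays positive definite.  One master
seed drives graph selection, the uniform draws and the normal samples
through documented substreams, so every experiment is bit-reproducible.

What the generator does *not* emulate: non-Gaussian tails, heteroscedastic
or dependent samples, hub/banded topologies, and any alternative-hypothesis
(power) design.  Passing simulation tests therefore show calibration under
the generator's Gaussian nulls, not robustness on real expression data.

## Simulation harness

[run_coverage_experiment()] repeats: draw truth, draw data, fit, test, and
record whether each 95% interval covers the true contrast (zero under all
three nulls).  Coverage is averaged over the support $S$ — the nonzero
entries of the reference combination, *including* the diagonal — and its
complement.  A fresh truth is drawn each replication (per-entry coverage is
then a frequency over all randomness); `redraw_truth = FALSE` fixes the
truth instead, and support membership is tracked per replication when it
varies.  Non-converged fits are redrawn from a fresh substream; more than
10% redraws aborts the run.  [run_fluctuation_experiment()] collects the
standardized statistic at chosen entries and summarizes with moments and a
Kolmogorov–Smirnov comparison to $N(0,1)$.

Problem sizes: the reference design is $p = 100$, $n \in \{200, 400\}$ per
group, 500 replications with per-replication AIC tuning on the full
$30\times 30$ grid.  The package's own test suite and the bundled
acceptance script use the scaled-down design — 100 replications at the
rate-based fixed penalty $\lambda = \rho = \sqrt{\log p / n}$ — which runs
in minutes and tracks the reference Equal-Null and complement averages to
within about 0.01–0.02.

## Limitations

* **Linear-null support coverage.** Under the `linear` null the average
  coverage over $S$ is systematically a few points higher (less
  under-coverage) than reference results produced with solvers that also
  fuse diagonal entries: diagonal fusion biases diagonal contrasts harder
  when diagonals differ by a multiplicative factor.  The off-diagonal-only
  penalty here is the formulation this package commits to.
* **Dense regimes.** With a dense ground truth ($\tilde\alpha$ near 1) the
  sparsity conditions behind the CLT fail, and the fitted matrix is
  multiplicatively shrunk ($\hat\Theta \approx c\,\Theta_0$, $c < 1$).  The
  statistic's fluctuation then has variance near $c^2 < 1$: the oracle
  statistic with the true $\Theta_0$ is calibrated, but the plug-in is
  conservative, and a KS test with a few hundred replications detects the
  deflation at some entries even though histograms look bell-shaped.
  Treat dense-regime $p$-values as conservative.
* Unequal group sizes use the per-group variance scaling described above,
  an interpretation beyond the equal-$n$ theory.
* Missing data are rejected, not imputed; there is no missing-data theory
  for this estimator.
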
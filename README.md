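# fglinfer

Joint estimation of multiple sparse Gaussian precision matrices with the
fused graphical lasso (FGL), and de-biased entrywise hypothesis tests and
confidence intervals for linear combinations of precision-matrix entries
across groups.

## Who this is for

In a Gaussian graphical model the precision (concentration) matrix
Θ = Σ⁻¹ encodes conditional independence: Θᵢⱼ = 0 exactly when variables
i and j are independent given the rest.  When the same variables are
measured in several related groups — e.g. gene-expression profiles of
disease subtypes — the scientific question is often *differential*: which
pairwise conditional dependencies change between groups?  This package
estimates all K group networks jointly and then tests, entry by entry,
hypotheses of the form

    H0 : a1 Θ⁽¹⁾ᵢⱼ + … + aK Θ⁽ᴷ⁾ᵢⱼ = 0,

with a = (1, −1) giving the two-sample equality test.

## Method

**Estimation.**  The FGL minimizes, over symmetric positive-definite
matrices,

    Σₖ { tr(Σ̂⁽ᵏ⁾ Θ⁽ᵏ⁾) − log det Θ⁽ᵏ⁾ }
      + λ Σₖ ‖offdiag(Θ⁽ᵏ⁾)‖₁ + ρ Σ_{k<k'} ‖offdiag(Θ⁽ᵏ⁾ − Θ⁽ᵏ'⁾)‖₁ ,

solved by a consensus ADMM whose Θ-update is an eigenvalue closed form and
whose Z-update is an exact entrywise fused-lasso proximal operator
(complete-graph total variation via isotonic regression, then
soft-thresholding).  A weighted variant fits on sample correlation
matrices and back-transforms.  (λ, ρ) can be tuned by AIC over a grid
(default 30 points from 0.05 to 0.3 per axis).

**Inference.**  Because penalized estimates are biased, tests use the
de-biased (de-sparsified) estimator

    Θ̂_d = 2 Θ̂ − Θ̂ Σ̂ Θ̂ ,

whose entries are asymptotically normal.  The contrast statistic
Tᵢⱼ = Σₖ aₖ Θ̂_d⁽ᵏ⁾ᵢⱼ is standardized by
se²ᵢⱼ = Σₖ aₖ² [Θ̂⁽ᵏ⁾ᵢᵢ Θ̂⁽ᵏ⁾ⱼⱼ + (Θ̂⁽ᵏ⁾ᵢⱼ)²] / nₖ, giving z-scores,
two-sided normal p-values, and confidence intervals
Tᵢⱼ ± z_{1−α/2} · seᵢⱼ.

A seeded simulator builds sparse positive-definite ground truths (sparsity
parameter α̃, nonzero magnitudes in [0.5, 1), minimum eigenvalue 0.1) and
harnesses reproduce coverage and normality (fluctuation) experiments.

## Worked example

Two groups whose precision matrices are proportional (Θ⁽²⁾ = 0.5 Θ⁽¹⁾), so
the contrast (1, −2) is zero everywhere — a true null:

```r
library(fglinfer)

truth <- make_null_scenario("linear", p = 30, alpha_tildes = 0.1,
                            coeffs = 0.5, seed = 42)
data  <- sample_groups(truth, group_sizes = 150, seed = 42)
covs  <- sample_covariance(data, center = FALSE)
fit   <- fgl_admm(covs, fgl_penalty(lasso = 0.15, fusion = 0.1))
fit
#> precision_set (plain): K = 2, p = 30, lambda = 0.15, rho = 0.1
#>   converged in 99 iterations (primal 0.000291, dual 3.57e-05)

res <- linear_test(fit, covs, contrast_spec(c(1, -2)))
res
#> fgl_test_result (plain): p = 30, contrast = ( 1, -2), alpha = 0.05
#>   rejected off-diagonal pairs: 11 of 435

true_contrast <- truth$precisions[[1]] - 2 * truth$precisions[[2]]
mean(res$ci_lower <= true_contrast & true_contrast <= res$ci_upper)
#> [1] 0.9666667
```

The fit converged in 99 ADMM iterations.  Under this null, 11 of 435
variable pairs are (falsely) rejected at α = 0.05 — close to the ~22
expected from the nominal level, with the deficit reflecting the method's
mild conservatism — and 96.7% of the entrywise 95% confidence intervals
cover the true (zero) contrast.  `res$pvalues`, `res$zscores`,
`res$ci_lower`/`res$ci_upper` are symmetric p × p matrices;
`write_results()` exports them as CSV with a metadata JSON.

For shell use, `inst/cli/fglinfer.R` provides `simulate`, `fit`, `test`,
`coverage` and `fluctuation` subcommands (see its header for examples).

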
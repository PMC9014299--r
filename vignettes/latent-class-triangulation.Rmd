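---
title: "Estimating test operating characteristics without a gold standard"
author: "lcdiag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating test operating characteristics without a gold standard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcdiag)
```

## The problem

Suppose `K` different testing methods each deliver a yes/no call on the
same `n` hypotheses — in the motivating application, whether a human
complex trait is associated with a tissue, tested by several distinct
GWAS-plus-transcriptome strategies. The methods disagree, no error-free
reference ("gold standard") exists, and we would like to know how good
each method actually is: its sensitivity, its specificity, and what
fraction of the hypotheses are truly non-null.

With only two methods this is hopeless — the parameters are not
identifiable. With `K >= 3` *conditionally independent* methods it is
not: the joint distribution of the K binary calls has `2^K - 1` free
cells, enough to pin down the `2K + 1` unknowns. Conditional
independence means that, given the true status of a hypothesis, knowing
one method's call tells you nothing about another's. It is an
uncheckable assumption; it is plausible exactly when the methods rest on
genuinely different modelling logic, and it fails when two of the
"different" methods are variations of the same idea.

## The model

Let `A_i` be the unobserved truth for hypothesis `i` (`A_i = 1` with
prevalence `rho`), and let `Y_ik` be method `k`'s call. The parameters
are the sensitivities `phi_k = P(Y_ik = 1 | A_i = 1)` and false-positive
rates `psi_k = P(Y_ik = 1 | A_i = 0)`; specificity is `1 - psi_k`.
Under conditional independence the marginal probability of a joint call
pattern `y = (y_1, ..., y_K)` is the two-component mixture

    P(y) = rho * prod_k phi_k^y_k (1-phi_k)^(1-y_k)
         + (1-rho) * prod_k psi_k^y_k (1-psi_k)^(1-y_k)

and the likelihood of the data is the product of `P(y_i)` over
hypotheses. Since the likelihood depends on the data only through the
counts of the `2^K` patterns, all fitting in this package operates on a
`pattern_table()`; one likelihood evaluation costs `O(2^K)` regardless
of `n`.

```{r fit}
truth <- list(rho = 0.3, phi = c(0.35, 0.85, 0.8), psi = c(0.15, 0.65, 0.2))
sim <- sim_binary(5000, truth$rho, truth$phi, truth$psi, seed = 1)
fit <- lc_fit(sim$Y)
fit
```

## Numerical choices

**Optimization.** `lc_fit(method = "ml")` maximizes the log-likelihood
by BFGS on the *logit* scale of all `2K + 1` parameters, with an
analytic gradient. The unconstrained parameterization removes the
boundary failures a box-constrained optimizer hits when an estimate
wants to sit at 0 or 1. The mixture likelihood is multimodal in
principle, so the optimizer is multi-started: one moment-flavoured start
(prevalence 0.5; each method's sensitivity a little above, and
false-positive rate a little below, its raw positive-call rate) plus 19
uniform-random starts by default, keeping the best optimum and polishing
it with a restart. Pattern probabilities are clipped to
`[1e-10, 1 - 1e-10]` inside the likelihood so degenerate data cannot
produce `log(0)`.

**The EM route.** `lc_fit(method = "em")` implements the standard
expectation-maximization iteration for a two-class latent class model:
the E-step computes `P(A = 1 | pattern)` at current parameters, the
M-step re-estimates all parameters as weighted positive-call rates. Its
log-likelihood is non-decreasing by construction (tolerance `1e-10` per
iteration, at most 10,000 iterations). EM is retained as an
algorithmically independent cross-check of the quasi-Newton route; the
test suite requires the two to agree to `1e-4` per parameter on dozens
of seeded datasets.

**Label switching.** The likelihood is exactly invariant under swapping
the latent classes, `(rho, phi, psi) -> (1 - rho, psi, phi)`. Every fit
resolves the ambiguity by the convention `sum_k (phi_k - psi_k) >= 0`
(nonnegative summed Youden index): the methods are assumed jointly
informative rather than jointly anti-informative. `label_swapped`
records whether the swap was applied.

**Identifiability guards.** `K < 3` is a hard error. Fewer rows than
parameters, or a dataset in which every row shows the same pattern, earn
warnings; the latter legitimately drives estimates to the boundary.

## Uncertainty

`lc_boot()` attaches standard errors by resampling hypotheses (rows,
never methods) with replacement, refitting each replicate, and taking
the per-parameter standard deviation across replicates; 99 replicates by
default. Replicate resampling seeds are derived from the root seed and
the replicate index, so any single replicate can be reproduced; the
refit itself is seeded identically across replicates so that a
replicate's estimate depends only on its resampled data. Replicates that
fail to fit are dropped with a warning and the effective count reported.
Only standard errors are reported — no percentile or BCa intervals.

```{r boot}
bt <- lc_boot(sim$Y, B = 30, seed = 2, fit = fit)
bt
```

## Combining the methods

Given fitted operating characteristics, the calls are triangulated:

* **Association score.** `assoc_score()` computes
  `S_i = sum_k Y_ik (1 - psi_k) / sum_k (1 - psi_k)`: the summed
  specificity of the methods calling positive, normalized to `[0, 1]`.
  A positive from a high-specificity method is worth more.
* **Per-method FDR.** `method_fdr()` is the Bayes rate
  `psi_k (1 - rho) / (psi_k (1 - rho) + phi_k rho)`.
* **Per-pair FDR.** `pair_fdr()` is the posterior probability of no
  association given the full call pattern,
  `(1 - rho) L0 / ((1 - rho) L0 + rho L1)` with the class-conditional
  pattern likelihoods `L0`, `L1`. The prevalence enters once, not once
  per method: the per-pair and per-method formulas then agree exactly
  when the other methods are uninformative (their factors cancel), a
  coherence property the tests assert.
* **Overall FDR.** `overall_fdr()` averages `pair_fdr` over the pairs
  with `S_i > 0`, weighted by `rank_weights()`: the inverse-normal
  transform of the score mid-ranks plus one,
  `w_i = qnorm((r_i - 0.5)/n_pos) + 1`. Confident discoveries are
  up-weighted, marginal ones down-weighted, and for untied scores the
  raw weights sum exactly to the discovery count `n_pos`. Because
  `qnorm(0.5/n_pos) + 1 < 0` once `n_pos >= 4`, raw weights can be
  negative, which would let the "overall FDR" escape the convex hull of
  the per-pair FDRs; the default therefore clips weights at zero
  (`clip = FALSE` restores the exact-sum variant). Scores take at most
  `2^K` distinct values, so ties are the norm; average ranks are used
  and the clipped weight sum may then deviate slightly from `n_pos`.

`score_atlas()` assembles everything into one table per hypothesis pair
with a `significant` flag at pair-FDR < 0.05.

```{r atlas}
atlas <- score_atlas(sim$Y, fit)
head(atlas, 4)
attr(atlas, "overall_fdr")
```

## Threshold sweeps

Real inputs are p-value matrices, not calls. `binarize_pvalues()`
thresholds them (inclusively: `p <= t` is a positive), after
`drop_incomplete()` removes pairs not assessed by every method.
`lc_sweep()` repeats binarize → fit → bootstrap → score over a grid of
thresholds — by default the 18 cutoffs 0.01–0.09 and 0.1–0.9 — yielding
ROC-style tables of `(FPR, TPR)` per method with bootstrap whiskers, and
FDR-versus-discoveries summaries for each method and for the combined
score. Per-threshold fits are independent (no warm starts): slower, but
each row of the table is reproducible in isolation. Fits with a boundary
prevalence (outside `[0.01, 0.99]`), a method with zero positive calls,
or a sensitivity below the paired false-positive rate are flagged
`unstable` rather than suppressed.

## What the simulator emulates — and what it does not

`sim_binary()` draws `A_i` first and then conditionally independent
calls; marginalizing over `A` this is exactly the multinomial
pattern-sampling scheme the model assumes, and the equivalence (pattern
frequencies matching the model probabilities) is itself a test.
`sim_pvalues()` generates per-method p-values that are `Uniform(0,1)`
under the null and `Beta(a_k, 1)` under the alternative, so that
thresholding at `t` implies sensitivity `t^(a_k)` and false-positive
rate `t` — a closed-form ROC against which the whole
binarize-fit-sweep path is checked end to end.

The default study conditions are three methods with sensitivities
0.35 / 0.85 / 0.80 and specificities 0.85 / 0.35 / 0.80 — one specific
but insensitive method, one sensitive but unspecific, one good
all-round — at prevalence 0.3, with 100 simulation repeats and sample
sizes 1,000 / 10,000 / 100,000. The prevalence is this package's choice
of a realistic interior value; estimation efficiency degrades as `rho`
approaches the boundary, and the tests assert exactly that, rather than
hiding it.

What the simulator does **not** emulate: violations of conditional
independence (two methods sharing a modelling idea, or the same data
artifacts), method-specific p-value miscalibration under the null,
trait-specific prevalence, and any structure of real GWAS or expression
data. A clean pass of the simulation suite therefore validates the
estimator under its own assumptions; it cannot certify those
assumptions for a particular set of real methods.

## Problem sizes used by the test suite

The distributional checks run at the simulator's study conditions:
100 repeats at `n` = 100,000 (recovery of the generating values to
±0.02 in the mean), 100 repeats at `n` = 1,000 and 10,000 (monotone
shrinkage of the estimator's spread), 50 seeded datasets at `n` = 2,000
(quasi-Newton/EM agreement), and single datasets of `n` = 100,000 for
FDR calibration against the latent truth and for the matched-count
comparison of combined versus single-method FDR. Pattern-table fitting
makes each likelihood evaluation `O(2^K)`, so these sizes run in a few
minutes on one core.

## Known limitations

* Conditional dependence between methods is not modelled; estimates are
  biased when it is present, typically optimistically for the dependent
  methods.
* A single global prevalence is assumed. Per-stratum prevalences would
  need many more hypotheses per stratum to be estimable.
* The bootstrap reports standard errors only; whisker-style intervals
  inherit the usual caveats near parameter boundaries, where the
  sampling distribution is skewed.
* For `K = 3` a closed-form MLE exists in principle; this package uses
  the numeric routes (with the EM cross-check) for any `K >= 3`
  uniformly.
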
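---
title: "Quantile mediation analysis with high-dimensional mediators: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantile mediation analysis with high-dimensional mediators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`qmediate` addresses a common situation in molecular epidemiology: an
exposure $X$ (say maternal smoking), an outcome $Y$ (say birthweight), a
small set of covariates $Z \in \mathbb{R}^q$, and a very large panel of
candidate mediators $M = (M_1, \dots, M_p)'$ (say DNA-methylation beta
values, with $p$ in the hundreds of thousands and $p \gg n$).  Mean
regression summarizes how mediation shifts the *average* outcome; it says
nothing about whether mediation acts differently in the tails — for
example among low-birthweight newborns.  The quantile mediation model
targets a chosen level $\tau \in (0,1)$ of the outcome distribution:

$$M_k = c_k + \alpha_k X + \zeta_k' Z + e_k, \qquad k = 1, \dots, p,$$
$$Q_\tau(Y \mid X, M, Z) = c_\tau + \gamma_\tau X + \sum_k \beta_{k,\tau} M_k
  + \eta_\tau' Z.$$

The direct effect of a unit exposure contrast on the $\tau$-quantile is
$\gamma_\tau$ (the controlled direct effect is $\gamma_\tau(x - x^*)$), and
the mediated (controlled indirect) effect through $M_k$ is the product
$\alpha_k \beta_{k,\tau}$, summed over mediators for the total
$\sum_k \alpha_k \beta_{k,\tau}(x - x^*)$.  The working sparsity assumption
is that only a few mediators have $\alpha_k \beta_{k,\tau} \neq 0$ at any
given $\tau$; the goal is to find that set with familywise confidence and
to estimate its effects.  The causal reading additionally assumes the usual
no-unmeasured-confounding conditions and that mediators do not cause one
another (they may be correlated).

## The three-step procedure

**Step 1 — marginal screening.**  Mediators are standardized to unit
sample standard deviation so their coefficients are comparable, and each is
scored by its coefficient $\tilde\beta_k$ in the marginal quantile model
$Q_\tau(Y \mid X, M_k, Z)$.  The top
$d = 2\lfloor n / \log n \rfloor$ mediators by $|\tilde\beta_k|$ form the
screened set $I_\tau$ ($\lfloor\cdot\rfloor$ is the floor, $\log$ the
natural logarithm; ties break toward the lower column index, and $d$ is
additionally capped at $p$ and at $n - q - 3$ so later refits remain
overdetermined).  Screening of this marginal-ranking type retains strongly
active mediators with probability tending to one; genuinely weak paths can
fall below the noise ceiling of the $p - |\Omega_0|$ inactive marginal
coefficients, which is visible in the simulation results as a true-positive
proportion well below 1 at realistic signal sizes.

**Step 2 — penalized selection.**  On the screened design the procedure
minimizes smoothed check loss plus a minimax concave penalty (MCP)

$$\frac{1}{n}\sum_i \rho_\tau\!\big(Y_i - c - \gamma_\tau X_i -
  \textstyle\sum_{k \in I_\tau} \beta_{k,\tau} M_{ik} - \eta_\tau' Z_i\big)
  + \sum_{k \in I_\tau} p_{\lambda,\delta}(\beta_{k,\tau}),$$

with $p_{\lambda,\delta}(t) = \lambda(|t| - t^2/(2\delta\lambda))$ for
$|t| < \delta\lambda$ and $\lambda^2\delta/2$ beyond.  MCP is
quadratic-then-flat: unlike the LASSO it leaves large coefficients nearly
unbiased while still zeroing small ones.  Survivors (nonzero mediator
coefficients, tolerance $10^{-8}$ on the standardized scale) form
$S_\tau$.

Two design choices deserve note.  First, the penalty is applied to the
*mediator* coefficients only.  A literal reading of the criterion would
also penalize the intercept, $\gamma_\tau$ and $\eta_\tau$, but penalizing
the exposure would bias the direct effect the method reports, and the
companion-software convention for this model family keeps
exposure and covariates unpenalized.  Second, $\lambda$ must be tuned and
no rule is canonical; `qmediate` uses a high-dimensional BIC,
$\log(\text{mean check loss}) + |S_\tau| \log(d+q+2) \log(\log n)/(2n)$,
over a log-spaced path of 20 values from $\lambda_{\max}$ (the smallest
$\lambda$ with an empty survivor set, located from the score of the
mediator-free fit and verified by probing) down to
$0.01\lambda_{\max}$, with ties resolved toward the sparser fit.  HBIC is
the standard consistent choice for folded-concave penalties when
$p \gg n$.  The concavity default is $\delta = 3$, the conventional MCP
value.

**Step 3 — joint-significance testing.**  The survivor sub-model is refit
without penalty, giving $\hat\beta_{k,\tau}$ with sandwich standard errors,
and each survivor's exposure path is fit by OLS, giving $\hat\alpha_k$.
With two-sided normal p-values $P_{\alpha_k}$ and $P_{\beta_{k,\tau}}$,
the decision statistic is

$$D^{JS}_{k,\tau} = \min\!\big(d_\tau \max(P_{\alpha_k},
  P_{\beta_{k,\tau}}),\, 1\big), \qquad d_\tau = |S_\tau|,$$

and $\hat\Omega^{JS}(\tau) = \{k \in S_\tau : D^{JS}_{k,\tau} < 0.05\}$
(strict inequality, level configurable).  A path is declared only when
*both* of its legs are significant, and the $d_\tau$ factor is a
Bonferroni-type correction over the survivors, which is what keeps false
discoveries near zero in the simulations.  $d_\tau$ counts the Step-2
survivors, not the screened set or $p$.

## Numerical methods

*Smoothed quantile regression.*  The check loss is convolved with a
Gaussian kernel of bandwidth
$h = \max\{0.05, ((k + \log n)/n)^{2/5}\}$ ($k$ = number of
coefficients), the convention of convolution-smoothed ("conquer"-style)
quantile regression.  The smoothed objective is convex and twice
differentiable with gradient increment $\tau - \Phi(-r/h)$ per residual,
so unpenalized fits use damped Newton iterations from a least-squares
start (convergence: relative coefficient change $< 10^{-8}$, at most
500 iterations).  The penalized criterion is minimized by
majorize–minimize: the loss curvature is bounded by
$1/(h\sqrt{2\pi})$ per observation, giving a quadratic surrogate solved by
coordinate descent with the exact scalar MCP proximal rule
(soft-threshold-then-inflate inside $|z| < \delta\lambda$, identity
outside; well-defined because $\delta \times$ weight $> 1$ at the default
bandwidth).  The inner solver runs in covariance form with an active-set
strategy, and the $\lambda$ path is warm-started from sparse to dense.

*The Step-3 refit sharpens the bandwidth.*  Smoothing trades a small bias
(and variance reduction) for differentiability; that is appropriate for
screening and selection, but the reported coefficients and their p-values
should come from the exact check-loss minimizer, which is also what the
standard exact solver (`rq`-type) would produce.  The refit therefore
continues the bandwidth downward ($h$ halved with warm starts to
$10^{-4}$); the survivor model has only $|S_\tau| + q + 2$ coefficients,
so this costs little.  The test suite verifies agreement with an exact
basis-enumeration oracle to $10^{-5}$ on small instances.

*Standard errors.*  The refit uses a kernel sandwich estimator:
Powell's kernel estimate of the density-weighted Hessian with a
Hall–Sheather bandwidth for the density term, combined with the
$\tau(1-\tau) X'X/n$ outer matrix.  A pairs bootstrap is available as an
option and agrees with the sandwich within sampling error in the tests.
The exposure-path model uses classical OLS standard errors.  P-values are
two-sided normal, exactly as the decision statistic defines them, with no
small-sample $t$ correction.

*Degenerate inputs.*  Zero-variance mediators abort standardization with
the offending names; rank-deficient designs error; an empty $S_\tau$
yields a valid direct-effect-only result with an empty test table; rows
with missing values are dropped (and counted) at validation, since the
method itself has no missing-data mechanism.

## The simulation framework

`sim_config()`/`sim_generate()` reproduce the reference simulation
designs.  Mediator errors are drawn with AR covariance
$\Sigma_{ij} = 0.25^{|i-j|}$ via the stationary AR(1) recursion
(coefficient $0.25$, innovation sd $\sqrt{1 - 0.0625}$), which is exactly
equivalent in distribution to a Cholesky draw but linear in $p$.  The
exposure and both covariates are $N(0, 4)$ — the second argument read as a
*variance* (sd 2), the conventional reading; it is a config knob should a
different scale be wanted.  The covariate coefficient on the outcome is
$\eta = (0.5, 0.5)'$; the source material prints "(0.5,0,5)" for this
vector, an evident typographical slip for the symmetric pair (mediator
models use the symmetric $\zeta_k = (0.3, 0.3)'$), and the value is
configurable.  True coefficient vectors default to
$\alpha = (0.85, 1.2, 1, 0.15, -0.25, 0.65, -0.50, 0, \dots)'$,
$\beta = (0.85, 1.2, 1, 0.25, -0.15, 0, 0, 0.75, -0.5, 0, \dots)'$,
$\phi = (0.1, 0.1, 0.1, 0, \dots)'$, $\gamma = 0.5$, $\theta = 0.1$, so
the truly mediating set is $\{1, \dots, 5\}$ at every $\tau$ (mediators
6–9 have one path each and test the joint-significance logic).

Case I adds standard normal noise: the quantile-specific truth is
$\alpha_k \beta_k$ at every $\tau$.  Case II multiplies the noise by
$\theta X + \phi' M$, following the generating equation literally, so the
printed conditional-quantile form
$\beta_{k,\tau} = \beta_k + \Phi^{-1}(\tau)\phi_k$ holds where the
multiplier is positive and the two cases share every random draw under a
common seed (`sim_generate` exposes the latent components, and with
$\theta = 0, \phi = 0$ the Case II outcome is exactly the Case I outcome
minus its additive error).  Because the multiplier is centred near zero,
Case II data are *less* noisy than Case I at the median, which is why
selection is somewhat easier there.

What the generator does *not* emulate: bounded $[0,1]$ methylation-type
mediators (its mediators are Gaussian), binary exposures (possible via the
config but not part of the evaluated designs), batch structure, or
mediator-mediator causal pathways.  Passing the simulation suite therefore
supports correctness of the algorithmic pipeline and its operating
characteristics under the stated Gaussian designs, not robustness to
real-methylation artefacts.

The harness (`run_repetition`, `aggregate_metrics`, `run_study`) reports
per-mediator bias and sampling standard error (SSE), with non-surviving
mediators contributing an estimate of exactly 0, plus model size (MS),
true-positive proportion (TPP) and false-discovery proportion (FDP, 0 for
an empty selection), each with its Monte-Carlo standard error.
Repetition $r$ of cell $c$ uses seed
$\text{base} + (c-1) \cdot 10^5 + r$, so any repetition can be re-run in
isolation and parallel execution cannot change results.  The package's
evaluation runs use 100 repetitions per cell at $p = 3000$,
$n \in \{200, 300\}$ — the point where the Monte-Carlo standard errors
are already a small fraction of the metric values — and the comparison
tolerances in the test suite are three Monte-Carlo standard errors (a
relative band for SSE, itself a noisy quantity at this repetition count).
The one-mediator comparator scan (`single_mediator_scan`) implements the
marginal JS test with Bonferroni correction at reduced fidelity: the
cited single-mediator methods are external and not fully specified here,
so its numbers are sanity ranges rather than reproduction targets.

## Known limitations

- Single quantile level per fit; no crossing adjustment or joint
  inference across $\tau$.
- Point estimates only for the products $\alpha_k \beta_{k,\tau}$; no
  confidence intervals for mediated effects.
- No exposure–mediator interactions, survival or longitudinal outcomes.
- The screening rank statistic is $|\tilde\beta_k|$ as defined, not its
  $t$-statistic; with heteroscedastic mediators the two can order
  differently.
- The refit standard-error estimator (kernel sandwich) is a documented
  stand-in for the unspecified choice behind the reference
  implementation; the bootstrap option is provided for sensitivity
  checks.
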
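---
title: "Quantile residual-life regression with longitudinal covariates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantile residual-life regression with longitudinal covariates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qreslife)
```

## The model

For a failure time $T$, the residual life at a base time $t$ is $T - t$ given
$T \ge t$. In clinical follow-up the natural question is often not "what is the
hazard now" but "how much longer": the $\tau$-th quantile of the remaining time
for a patient who has survived to $t$, given their covariates. With time-fixed
covariates $W$ (here always including an implicit intercept) and a longitudinal
covariate vector $Z(t)$ measured at follow-up visits, `qreslife` fits

$$
\log Q_{T-t}\!\left(\tau \mid T \ge t, W, Z(t)\right)
  \;=\; \alpha(\tau, t)^\top W + \beta(\tau, t)^\top Z(t),
$$

a quantile regression of log residual life with coefficients that may change
with the base time $t$. Each coefficient function is expanded in a small basis,
$\alpha_j(t) = \sum_{l=0}^{L} a_{j,l} f_l(t)$ and likewise for $\beta_k(t)$, so
the whole fit reduces to one finite-dimensional parameter $\gamma$ stacking the
blocks $(a_{0,\cdot}, \ldots, a_{p,\cdot}, b_{1,\cdot}, \ldots, b_{q,\cdot})$.
The default basis is the fractional-polynomial set
$\{1, \log t, \sqrt{t}, 1/\sqrt{t}\}$; B-spline bases and two alternative
fractional-polynomial sets are available as presets. Terms such as $\log t$
diverge at $t = 0$, so coefficient functions are only evaluated at strictly
positive base times.

## Estimation

Right censoring ($Y = \min(T, C)$, $\delta = I(T \le C)$) is handled by inverse
probability of censoring weighting: uncensored residual-life indicators are
reweighted by $\hat G(t_j) / \hat G(Y_i)$, where $\hat G$ is the Kaplan–Meier
estimate of the censoring survival function (censorings treated as events,
failures as censored). Each subject contributes one term per *attended* planned
visit $t_j$ with $Y_i > t_j$, through the design row
$U_i(t_j) = (\xi(t_j), W_i \xi(t_j), Z_i(t_j)\xi(t_j))$ with
$\xi(t) = (f_0(t), \ldots, f_L(t))$. Missed visits simply drop out; this
assumes attendance is noninformative given covariates.

Two estimators share this structure:

* **Nonsmooth (exact L1).** The estimating equation is the subgradient of a
  censored, weighted least-absolute-deviation objective plus two
  pseudo-observations with a very large response $M$ (default $10^6$) whose
  design rows are fixed linear combinations of the data; minimizing it is a
  weighted median regression on the augmented data. `qreslife` solves this
  exactly with its own Frisch–Newton primal–dual interior-point solver
  (`qr_fit_ip()`), since no linear-programming quantile solver is among the
  package's dependencies. Every fit is certified post hoc: the estimating
  function at the solution must be componentwise bounded by the summed jumps of
  the residuals sitting at the solution's kinks, the subgradient condition of
  an exact L1 minimizer.

* **Induced smoothing (default).** Replacing the residual indicator by a
  standard-normal CDF with term-specific scale $\sqrt{U^\top H U}$ — the
  expectation of the nonsmooth function under a normal perturbation of
  $\gamma$ with covariance $H$ — gives a continuously differentiable system
  solved by damped Newton iteration with the analytic Jacobian, initialized at
  the nonsmooth estimate. The Jacobian uses the normal *density*; it is checked
  against finite differences in the test suite. Convergence is declared only
  when the sup-norm of the estimating function is below `qrl_control()$tol`
  (default $10^{-9}$), re-verified outside the solver.

### The smoothing matrix

$H$ must be symmetric positive definite with norm of order $1/n$. The package's
default is the Gram-standardized matrix

$$
H \;=\; \frac{h}{n} \left( \tfrac{1}{m} \textstyle\sum_{ij} U_{ij} U_{ij}^\top \right)^{-1},
\qquad h = 1 \text{ by default},
$$

rather than $I_d / n$. The reason is practical and visible in simulation: with
a raw identity, the bandwidth $\sqrt{U^\top H U / n}$ grows with $\|U\|$, which
differs systematically across covariate patterns (rows with $W = 1$ carry an
extra nonzero block) and across base times (the fractional-polynomial terms are
large near the ends of the visit window). The uneven bandwidth translates into
a small but systematic finite-sample bias in the affected coefficients, which
the nonsmooth estimator does not share. Standardizing by the average Gram
matrix makes the average squared bandwidth exactly $d/n$ regardless of basis
scaling and removes that differential bias; it also matches the spirit of
induced smoothing, where the perturbation is meant to mimic the estimator's
own sampling covariance. `h_scale` rescales the default, and an explicit `H`
overrides it.

Numerical details worth knowing: terms with $Y_i - t_j \le 0$ are excluded by
the at-risk indicator before logs are taken; positive residual times are used
exactly, however small. If $\hat G(Y_i) = 0$ for an observed failure (possible
only when the largest follow-up time is uncensored and beyond every censoring
time), the affected terms are dropped with a warning rather than producing
infinite weights. Ties between a failure and a censoring at the same time are
resolved with the failure first, so the censoring Kaplan–Meier's risk set at
its own jump excludes same-time failures. Newton steps are halved (up to 20
times) whenever they fail to reduce the estimating-function norm, and an
ill-conditioned Jacobian (condition number above $10^{12}$) triggers a
derivative-free polish instead of a Newton step.

## Variance estimation

The sandwich covariance
$\widehat{\mathrm{Var}}(\tilde\gamma) = (\tilde A^{-1})^\top \hat V \tilde A^{-1}$
combines the analytic slope matrix $\tilde A$ at the solution with a
multiplier-resampling estimate $\hat V$ of the estimating function's
variability: $K$ times (default 200), i.i.d. unit-mean exponential weights
$\theta_i$ are drawn, each subject's whole contribution is multiplied by its
$\theta_i$, the censoring Kaplan–Meier is refit with the same weights, and the
perturbed estimating function is re-evaluated at the fixed $\tilde\gamma$ — no
refitting of $\gamma$. $\hat V$ is the sample covariance of the $K$ replicates;
both $\tilde S$ and its perturbed versions carry the same $1/n$ prefactor, so
the assembled matrix estimates the covariance of $\tilde\gamma$ directly with
no extra factors of $n$. This convention is validated empirically: across
replications of the built-in designs, the average delta-method standard error
tracks the empirical standard deviation of the estimates within a few percent
(see the acceptance tests). Pointwise standard errors of $\hat\alpha_j(t)$ come
from the quadratic form $\xi(t)^\top \Sigma_{jj} \xi(t)$ on the corresponding
diagonal block, with Wald 95% limits.

A full multiplier bootstrap of the nonsmooth estimator (refitting the
perturbed L1 objective per replicate, censoring estimate perturbed alike) is
included as `nonsmooth_bootstrap_covariance()` purely as a slow reference
path; the test suite asserts only the ordinal claim that the sandwich route is
faster on the same instance.

## Prediction and its accuracy measures

`predict_residual_life()` exponentiates the fitted linear predictor at a base
time $t$ for a covariate profile, yielding the predicted $\tau$-th quantile of
the remaining time. Two accuracy measures are built in, both restricted to a
truncation time $L$ chosen slightly below the maximum censoring time (default:
the 95th percentile of the evaluation set's censoring times):

* `mae_p()`: mean absolute error between predictions and the *truncated* true
  residual life $\min(T_i - t, L - t)$ over subjects with $T_i > t$.
  Predictions are not truncated, only the truth — the literal definition. True
  failure times are available in simulation, which is where this measure is
  used.
* `c_index()`: truncated IPCW concordance — the weighted fraction of
  comparable pairs ($i$ uncensored, $0 < Y_i - t < Y_j - t$, $Y_i < L$, weight
  $\delta_i \{\hat G(Y_i)/\hat G(t)\}^{-2}$) whose predictions are ordered like
  their outcomes, ties counting as discordant. It is computed with the
  evaluation set's own censoring estimate and, internally, a Fenwick-tree
  sweep so large test sets stay $O(n \log n)$.

## The built-in study designs

Three generators drive validation; their defaults are the package's study
conditions and are not meant to be tuned.

* **Design I** (constant coefficients): $W \sim \mathrm{Bern}(0.5)$;
  exponential failure times with rate 1.5 when $W = 0$ and 1 when $W = 1$, so
  memorylessness makes the true coefficient functions constant:
  $\alpha_0(\tau) = \log(-\log(1-\tau)/1.5)$, $\alpha_1 = \log 1.5 \approx
  0.41$, and a pure-noise $Z(t) \sim \mathrm{Unif}(-1, 1)$ with $\beta = 0$.
  Censoring is $\mathrm{Unif}(0, 4)$ with probability 0.9 and the constant 4
  otherwise (about 19% censoring). Twelve planned visits at
  $0.1, 0.15, \ldots, 1.0$; attendance is Bernoulli with probability 0.75
  ($W=0$) or 0.9 ($W=1$), gated by being in follow-up.
* **Design II** (time-varying coefficients): failure survival
  $\exp(-\lambda t^2)$ with $\lambda \sim \mathrm{Unif}(0.5, 1.5)$; the
  residual-life quantile is $\sqrt{-\log(1-\tau)/\lambda + t^2} - t$ in closed
  form, and the biomarker is the deterministic transform of $\lambda$ that
  makes the model exact with $\alpha_0(t) = \log t$, $\alpha_1 = 0$,
  $\beta(t) = \sqrt t$. Attendance probabilities (0.5, 0.7); about 21%
  censoring.
* **Design III** (misspecified): as II but with
  $\beta(t) = 0.1(t+1)^2 + 0.1/t$, deliberately outside the span of the
  default basis, to probe robustness to structural misspecification.

Designs II and III consume their random numbers in the same order, so a shared
seed yields identical failure, censoring and attendance streams — only the
biomarker differs.

What these generators emulate: scheduled longitudinal measurement with
missed visits, covariate-dependent attendance, and administratively bounded
censoring. What they do not: irregular per-subject visit times,
covariate-dependent censoring, measurement error in the biomarker, or
informative missingness — so green tests here say nothing about those
complications in real cohorts.

## Replication drivers and problem sizes

`run_simulation_study()` repeats generate/fit/summarize and reports, per
(quantile, base time, coefficient): the truth, empirical bias (EB), the
empirical standard error (ESE) of the estimates, and the average estimated
standard error (ASE). `run_prediction_study()` fits on training sets and
scores `mae_p` and `c_index` on independent test sets. The package's own
validation uses 200 replications at $n = 400$ (with $K = 200$ resampling
replicates) for the bias/variance tables, and 100 replications with test sets
of $n = 2000$ for the prediction study; these sizes give Monte-Carlo standard
errors a few times smaller than the effects being checked while keeping the
whole suite comfortably runnable on one CPU. At these scales the EB of a
single cell is itself a noisy quantity (MC standard error $\approx$ ESE/14);
the acceptance checks therefore compare each cell's EB against twice its own
Monte-Carlo standard error, and small boundary-cell biases of order 0.02 — on
the same order as what the exact nonsmooth estimator shows at $n = 400$ — can
sit at the edge of that band.

## Design choices that were genuinely open

* **Visit schedule.** Visits live on a shared planned grid gated by attendance
  indicators; per-subject irregular times are out of scope.
* **Pseudo-observation coefficient.** The third pseudo-observation of the L1
  objective carries the coefficient $2\tau$; with it, the objective's gradient
  is exactly twice the estimating function (a test asserts this identity
  numerically), which is what makes the LP route and the estimating-equation
  route the same estimator.
* **Truncation time.** "Slightly below the maximum censoring time" is
  operationalized as the upper 5% point of censoring times, overridable.
* **Solver and initializer.** Newton-from-the-nonsmooth-estimate is the
  package's choice; nothing in the estimating equations forces it. The
  root-verification invariant (sup-norm of the estimating function at the
  returned solution) is what actually certifies a fit, not the solver path.
* **Degenerate IPCW weights.** Dropped with a warning, never silently floored:
  under the built-in designs censoring has bounded support, so this is a guard
  rather than a code path that shapes results.

## Limitations

Censoring must be independent of the covariates in the model (the weight is a
marginal Kaplan–Meier); a covariate-dependent censoring model is not
implemented. Multiple quantiles are fit independently, so fitted quantile
curves can cross. The basis is global in $t$: a misspecified shape (design III)
shows the estimator remains nearly unbiased at interior base times, but
extrapolation beyond the visit window is not supported.
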
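---
title: "Shape inference for the exponentiated half-logistic distribution from lower records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape inference for the exponentiated half-logistic distribution from lower records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehldrec)
```

## The model and the data structure

A lower record sample $x_{L(1)} > \dots > x_{L(k)}$ keeps only the running
minima of an i.i.d. series.  Under an exponentiated half-logistic parent,
$F(x) = \tanh(\theta x/2)^\lambda$, the whole record likelihood factors
through two reductions: the sum of the record values, and the statistic

$$h_1(\theta) = -\log F_0(x_{L(k)};\theta) = -\log\tanh(\theta x_{L(k)}/2),$$

the negative log of the *baseline* ($\lambda = 1$) CDF at the smallest
record.  Two facts organise everything this package does:

1. $\lambda\,h_1(\theta)$ is Gamma$(k, 1)$ at the true parameters, because
   the negative log CDF values of successive lower records are partial sums
   of standard exponentials.
2. The ratios $U_j = (T_j/T_{j+1})^j$ of those partial sums are i.i.d.
   Uniform(0,1) and do not involve $\lambda$, so
   $W(\theta) = -2\sum_{j<k}\log U_j \sim \chi^2_{2k-2}$ is a
   *shape-free* pivot for the nuisance scale.

The shape $\lambda$ is the parameter of interest; $\theta$ is a nuisance.
The package offers three ways of dealing with it — profiling (maximum
likelihood), pivoting it out ($W$), and MAP plug-in (Bayes) — so that their
small-sample behaviour can be compared on equal terms.

## Estimators

**Profile ML.**  The $\lambda$-score gives $\hat\lambda(\theta) =
k/h_1(\theta)$ in closed form, so the joint MLE reduces to a 1-D search on
the profile log-likelihood in $\theta$ (golden-section/parabolic on a
log-spaced bracket $[10^{-6}/\bar x,\,100/\bar x]$, followed by Newton
polish of the profile score to residual $10^{-10}$).  Wald intervals use
the *expected* information, whose $\theta$-block requires the series
$Q_1(\lambda), Q_2(\lambda)$ (below).  Even with $\theta$ known,
$\hat\lambda(\theta)$ is inverse-gamma distributed with bias
$\lambda/(k-1)$ — at $k = 10$ an 11% upward bias — which is the basic
motivation for the alternatives.

**Pivotal.**  With $\theta$ known, $\hat\lambda_p(\theta) =
(k-1)/h_1(\theta)$ is exactly unbiased with MSE $\lambda^2/(k-2)$, and
$2\lambda h_1 \sim \chi^2_{2k}$ inverts to an exact interval.  With
$\theta$ unknown, $\hat\theta_p$ solves $W(\theta) = 2k-4$ (the $\chi^2$
mode-matching equation; $W$ is strictly increasing in $\theta$, so the
root is unique) and is plugged in.  The generalized-pivotal interval
simulates the pivot with the scale integrated out: draw
$W \sim \chi^2_{2(k-1)}$, solve $W(\theta^*) = W$, draw
$2T_k \sim \chi^2_{2k}$, and keep $T_k/h_1(\theta^*)$; the empirical
$\alpha/2$ and $1-\alpha/2$ percentiles (type 7) of $N$ such draws form
the interval.  Its coverage is exact for every $k \ge 2$ by construction.

**Bayes with MAP plug-in.**  A Gamma$(\alpha,\beta)$ prior on $\lambda$ is
conjugate given $\theta$; the conditional reference prior on the scale is
$1/\theta$.  Integrating $\lambda$ out gives a marginal posterior for
$\theta$, whose mode is plugged into the conditional $\lambda$-posterior:

* vague model ($\alpha = \beta = 0.01$ by default): the plug-in posterior
  is Gamma$(k+\alpha,\ \beta + h_1(\hat\theta_{MAP}))$; as
  $\alpha,\beta \to 0$ its mean and mode recover the known-scale MLE and
  the unbiased estimator respectively;
* hierarchical model: $\lambda|\beta \sim$ Exp$(\beta)$ with
  $\beta \sim$ Uniform$(0, c)$, giving prior
  $\propto \lambda^{-2}[1-(1+c\lambda)e^{-c\lambda}]$.  The plug-in
  posterior is a mixture of three gamma kernels with closed-form
  normalizer $h_2 = h_1^{1-k} - (ck+h_1)/(c+h_1)^k$, mean
  $(k-1)h_3/h_2$, and a CDF expressible in regularized incomplete gamma
  functions (no MCMC anywhere).  As $c \to \infty$ the posterior mean
  tends to the pivotal unbiased estimator, and for moderate $c$ the
  estimates are insensitive to it — that robustness is the point of the
  hierarchy.

## Numerical choices

**Stable transforms.**  All record formulas reduce to
$T(u) = -\log\tanh(u/2)$.  It is evaluated in three regimes: the
asymptote $\log(2/u)$ for $u < 10^{-8}$ (where $e^{-u}$ rounds to 1), the
`log1p` form in the bulk, and $\log T = \log 2 - u$ for $u > 30$, so that
$\log T$ stays representable even where $T$ itself underflows.  $W(\theta)$
is computed from $\log T_j$ directly and is therefore usable over the whole
bracket the root-finders need.

**Information series.**  $Q_1, Q_2$ are evaluated from their series
expansions with cumulative inner harmonic and alternating-harmonic sums,
in chunks of 1024 terms, truncating when a chunk's largest term — weighted
by the $\lambda$-power it actually carries in $Q_1/Q_2$ — falls below
`tol` ($10^{-12}$ by default, cap $10^6$ terms; exceeding the cap is an
error, never a silent result).  The weighting matters: the per-record
series decay like $j^{-i}$, so the $i = 1$ component converges slowly and
must not inherit the $\lambda^{k+1}$ weight of the fast components.  The
series were validated against Monte-Carlo expectations of the analytic
second derivatives of the log-likelihood (the test suite keeps this check
at a 3-standard-error criterion).

**Solving $W(\theta) = w$ in bulk.**  The GPQ interval needs thousands of
roots per sample.  The solver brackets by geometric expansion, seeds all
roots at once with a monotone (Hyman) spline of $\log\theta$ against $W$
on a 200-point grid, polishes with vectorized Newton steps using the
analytic $dW/d\theta$, and falls back to bisection for any straggler; the
residual tolerance is $10^{-10}$.

**Interior MAP modes.**  Both marginal $\theta$-posteriors inherit an
integrable spike at $\theta \to 0$ from the $1/\theta$ prior (the density
diverges like $1/(\theta \log^{k-1}(1/\theta))$ while remaining
integrable), so a global maximizer is degenerate at the origin.  The
meaningful estimate is the *interior stationary point*, and that is what
`theta_map()` returns: local maxima are located on a 257-point log-spaced
scan of $[10^{-4}/\bar x,\ 10^4/\bar x]$ and refined to $10^{-12}$.  On
flat likelihoods — typically when the smallest record is very close to
zero — no interior mode exists at all; `theta_map()` then returns `NA`
with a warning, and the simulation engine records the replicate as a
failure for that estimator (see below).

**Hierarchical normalizer orientation.**  Integrating the joint posterior
over $\lambda$ analytically puts $h_2(\theta)$ in the *numerator* of the
marginal $\theta$-posterior; an alternative form with $h_2$ inverted
circulates and is exposed as `form = "printed"` for comparison, but it has
no interior mode on real data (its density decreases monotonically away
from the origin spike), while the integrated form reproduces the published
rainfall estimates ($\hat\theta_{HMAP} = 0.137$, posterior mean 5.891).
The integrated form is therefore the default.

**Credible intervals.**  Both equal-tail and highest-posterior-density
intervals are available.  HPD is the default: the posteriors are
right-skewed gammas (or gamma mixtures), where HPD is shorter and is what
reproduces the published interval lengths (hierarchical 7.43 at $c = 5$
versus 7.62 equal-tail).  HPD is computed by minimizing
$q(p + \gamma) - q(p)$ over the left tail mass $p$ at fixed coverage
$\gamma$.

## The synthetic-data generator

`rehld_records(k, theta, lambda)` uses the exact exponential-spacings
construction: $Z_i = -\log F(X_{L(i)})$ is a cumulative sum of $k$
standard exponentials and $X_{L(i)} = F^{-1}(e^{-Z_i})$.  This is the
record process *exactly* — no rejection, no approximation — so simulated
samples carry the true joint law, including the heavy lower tail of the
smallest record (about 8% of $k = 10$ samples at $\lambda = 2$ have
$x_{L(k)}$ so small that the MAP estimators' interior mode disappears;
this is a feature of the model, not an artifact).  What the generator does
*not* emulate is anything outside the model: measurement error,
serial dependence of the underlying series, or misspecification of the
parent family.  Passing tests therefore validate the estimators under the
model, not the EHLD's fit to any particular data set.

The evaluation engine (`run_sim_cell`, `run_sim_table`) uses defaults
matching the study design the estimators were built for: standard EHLD
($\theta = 1$), $\lambda \in \{2,4,6,8\}$, $k \in \{10,12,14,16\}$,
$c \in \{5,100,500\}$, vague hyperparameters 0.01, level 0.95, 10,000
replications.  MSE and bias are reported on the relative
($\hat\lambda/\lambda$) scale, with absolute-scale columns alongside, and
every column carries its Monte-Carlo standard error.  One integer seed
determines the whole table; per-cell sub-seeds are derived
deterministically from it.  Failure policy: no replicate is discarded or
re-drawn — conditioning the sample on estimator success would bias the
frequentist columns and break the exactness of the pivotal coverage — the
affected Bayes estimator simply records `NA` and the `fail_*` fractions
are reported with the cell.

Default problem sizes in the shipped checks are scaled to run unattended:
the test suite uses 1,000-replicate cells and $10^5$-draw sampling-law
checks; the reproduction script uses 5,000 replicates and a 10,000-draw
GPQ interval.  Larger runs are a matter of raising `reps`.

## Known limitations

* The Jeffreys and reference priors are implemented as densities (with
  their positivity constraint $[\lambda Q_2]^2/Q_1 < k$ checked and
  signalled), but no posterior inference is built on them; the constraint
  tightens as $\lambda$ grows, which is what makes them unattractive here.
* The MAP plug-in approximates the marginal $\lambda$-posterior by its
  conditional at a point estimate of $\theta$; it does not propagate
  $\theta$-uncertainty.  That is the method being studied, not a shortcut.
* For samples whose marginal $\theta$-posterior has no interior mode, the
  Bayes estimators are undefined and reported as such.
* Upper records, other parents in the proportional-reversed-hazard family,
  and prediction of future records are out of scope.
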
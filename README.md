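# ehldrec

Inference for the **exponentiated half-logistic distribution (EHLD)** when
the data are **lower record values** — the strictly decreasing subsequence
of running minima of an i.i.d. series, as arises with annual rainfall
minima, lifetime minima in repeated life tests, or record low temperatures.
The EHLD has CDF

    F(x) = ((1 - exp(-θx)) / (1 + exp(-θx)))^λ = tanh(θx/2)^λ,   x > 0,

with shape `λ > 0` (the parameter of interest: the density is decreasing
for `λ ≤ 1`, right-skewed unimodal for `λ > 1`) and reciprocal scale
`θ > 0` (a nuisance).  Because records are rare, a record sample is tiny
(`k ≈ 10`), and plain maximum likelihood is noticeably biased; the package
implements, side by side:

* **Profile maximum likelihood** — `λ(θ) = k/h₁(θ)` in closed form, with
  `h₁(θ) = -log tanh(θ x₍ₖ₎/2)`, a 1-D profile search in `θ`, and Wald
  intervals from a series expansion of the expected Fisher information
  (`I₁₁ = k/λ²`, `I₁₂ = Q₂(λ)/θ`, `I₂₂ = Q₁(λ)/θ²`).
* **Pivotal-quantity estimation** — `λ·h₁(θ) ~ Gamma(k, 1)` at the true
  parameters, giving the unbiased estimator `(k-1)/h₁(θ)`, an exact
  χ²-interval for known `θ`, the scale estimate solving `W(θ) = 2k-4`
  where `W(θ) ~ χ²₂ₖ₋₂` is shape-free, and a generalized-pivotal (GPQ)
  Monte-Carlo interval for `λ` with `θ` unknown.
* **Bayesian estimation with MAP plug-in** — a vague Gamma(α, β) prior on
  `λ` (conjugate given `θ`) and a robust hierarchical prior
  `λ|β ~ Exp(β)`, `β ~ Uniform(0, c)`, each combined with the conditional
  reference prior `1/θ`; the nuisance is eliminated by plugging the
  interior mode of its marginal posterior into the conditional
  `λ`-posterior, which is exactly Gamma (vague) or a three-term gamma
  mixture (hierarchical) with closed-form CDF.
* A **Monte-Carlo evaluation engine** comparing all four shape estimators
  (relative MSE and bias) and both interval procedures (coverage), and a
  small **CLI**.

## Worked example

The packaged fixture contains the ten lower records of annual rainfall
(inches) at the Los Angeles Civic Center, seasons 1877–2012:

```r
library(ehldrec)
rain <- read_records(system.file("extdata", "la_rainfall_records.txt",
                                 package = "ehldrec"))
ehld_report(rain, gpq_draws = 10000, seed = 1)
```

```
EHLD record-value analysis (k = 10 records)

Scale (theta) estimates:
      mle   pivotal       map   hmap_c5 hmap_c100 hmap_c500
    0.184     0.138     0.155     0.137     0.137     0.137

Shape (lambda) estimates:
      mle   pivotal     bayes   hier_c5 hier_c100 hier_c500
    7.996     5.897     7.051     5.890     5.890     5.890

95% intervals for lambda (hpd credible intervals):
  wald               (1.433, 14.560)   length 13.127
  gpq                (2.736, 15.463)   length 12.727
  bayes_vague        (3.028, 11.494)   length 8.466
  bayes_hier_c5      (2.371, 9.802)   length 7.431
  ...
```

Reading: the joint MLE `λ̂ = 8.0` is pulled up by its small-sample bias
(`≈ λ/(k-1)` even with `θ` known); the pivotal and hierarchical-Bayes
estimates agree near `5.9` and are the ones to trust at `k = 10`.  The
Wald interval is the widest (and can go negative at lower levels); the
hierarchical credible interval is the shortest, and is essentially
unchanged for `c` between 5 and 500 — the hierarchical prior is doing its
robustness job.  The same analysis is available from a shell:

```sh
Rscript inst/scripts/ehldrec report inst/extdata/la_rainfall_records.txt --seed 1
```

A Monte-Carlo comparison at chosen study conditions:

```r
run_sim_cell(lambda = 2, k = 10, sim_config(reps = 1000, c_list = 5, seed = 1))
```

returns relative MSE/bias for the four estimators, Wald and GPQ coverage,
Monte-Carlo standard errors, and the fraction of replicates whose
marginal-posterior mode does not exist (see the vignette).

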
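---
title: "Adjusting odds ratios for differential exposure misclassification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adjusting odds ratios for differential exposure misclassification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oradjust)
```

## The problem

Case-control studies of occupational exposures often rely on self-report,
and recall can differ between cases and controls — *differential*
misclassification. With binary exposure, the measurement process is fully
described by four probabilities: sensitivity and specificity of self-report
within each case status,

* `Se_g = P(report exposed | truly exposed, group g)`
* `Sp_g = P(report unexposed | truly unexposed, group g)`.

The apparent exposure proportion `q` in a group with true prevalence `p`
follows the identity `q = p*Se + (1 - p)*(1 - Sp)`. When a validation
subsample with a gold standard (e.g. payroll records checked against
self-reported night-shift work) is available, `Se` and `Sp` can be
estimated — but only with uncertainty, and ignoring that uncertainty is the
central pitfall this package addresses. `oradjust` implements three
adjustments of increasing fidelity and puts them side by side:

1. **Fixed-value correction** (`correct_counts()`, `odds_ratio_ci()`):
   valid only if `Se`/`Sp` are known exactly;
2. **Probabilistic bias analysis** (`run_pba()`): Monte-Carlo repetition of
   the correction with `Se`/`Sp` drawn from distributions, producing a
   simulation interval (a collection of alternative estimates, not a
   posterior);
3. **Bayesian misclassification model** (`run_mcmc()`): full posterior
   inference for the true odds ratio; the only one of the three whose
   interval is interpretable as a distribution of true values given data,
   model and priors.

## Prior elicitation from validation counts

For a validated proportion with `k` successes in `N` trials and complete
prior ignorance, the conjugate update gives `Beta(k + 1, N - k + 1)`
(`derive_beta()`). From a validation cross-tabulation, sensitivity uses the
gold-standard "ever" column and specificity the "never" column
(`priors_from_crosstab()`). The bundled night-shift validation counts give:

```{r}
v <- nightshift_validation()
priors <- priors_from_crosstab(v$cases, v$controls)
priors
```

Internally everything is a raw proportion; the percent formatting seen
above lives only in the print method, which avoids unit bugs. The uniform
`Beta(1,1)` starting prior is the default ("completely ignorant"); a
Jeffreys variant is available via `derive_beta(k, N, prior = "jeffreys")`
but is off by default. Note that this workflow deliberately replaces
bootstrap estimation of `Se`/`Sp` distributions: the Beta conjugate form is
simpler, exact, and composes directly with both the probabilistic and the
Bayesian machinery.

## Fixed-value correction and the rounding pitfall

`correct_counts()` inverts the apparent-prevalence identity per stratum:
with case margin `M1 = a + b`,

```
A = (a - (1 - Sp_cases) * M1) / (Se_cases + Sp_cases - 1),  B = M1 - A
```

and analogously for controls. It requires `Se + Sp > 1` per stratum (the
identifiability region; below it the correction formula points at the
mirror solution) and rejects corrections that produce negative expected
counts. Margins are conserved exactly, and the corrected cells are
**expected counts — they do not have to be integers**. `odds_ratio_ci()`
computes the Woolf (log-OR normal approximation) interval on those
non-integer cells. Rounding them to integers first, as spreadsheet-style
workflows invite, changes both the point estimate and the interval width;
`rounding_pitfall_report()` computes both side by side. The rounding mode
mimics spreadsheets (half away from zero) and exists only for that
demonstration.

Deliberately, no variance inflation for uncertainty in `Se`/`Sp` is added
here: the fixed-value CI reflecting *only* random error is exactly the
deficiency the other two methods repair, and the package exists partly to
display that contrast. Zero cells are an error by default (a 0.5
continuity correction is available but off, since none of the motivating
tables contain zeros).

## Probabilistic bias analysis

`run_pba()` repeats the correction `n_iter` times (default 100 000) with
quadruples `(Se_cases, Sp_cases, Se_controls, Sp_controls)` drawn by
`sample_correlated_betas()`: a Gaussian copula whose marginals are exactly
the four elicited Betas. The default correlation `rho = 0.1` (weak) links
sensitivity(cases) with sensitivity(controls) and specificity(cases) with
specificity(controls), with sensitivity-specificity independence — the
convention of standard probabilistic-bias-analysis software for
differential misclassification; which pairs carry the correlation is
configurable. At `rho = 0.1` the induced rank correlation (0.0955)
differs negligibly from the raw one.

Draws outside the identifiability region or producing a non-positive
corrected cell are **rejected and counted** (`n_rejected`), never
truncated — truncation would silently distort the marginals. (Zero cells
are folded into the rejection rule because their log-OR is undefined.)
Conventional random error is then added on the log-OR scale,
`log OR_i - z_i * SE_conv`, with `SE_conv` the Woolf standard error of the
observed table — the summary-level convention; it can be switched off to
isolate systematic uncertainty. The retained draws are summarized by the
median and a central percentile interval (linear interpolation between
order statistics, quantile type 7).

## The Bayesian model

The likelihood conditions on the case-control margins:

```
a ~ Binomial(M1, q1),  q1 = p1*Se_cases + (1 - p1)*(1 - Sp_cases)
c ~ Binomial(M0, q0),  q0 = p0*Se_controls + (1 - p0)*(1 - Sp_controls)
```

with `p1 = expit(logit(p0) + theta)` — the case prevalence is a derived
quantity, not a free parameter, so the priors are exactly: uniform on the
control prevalence `p0`, a null-centred normal on the log odds ratio
`theta`, and four independent Betas on the misclassification parameters
(no correlation is imposed between them). The default
`logor_prior_sd = ln(50)/1.96 ≈ 1.996` makes the prior OR 95% interval
exactly (0.02, 50), a vague choice suited to sparse-data problems; the
interval, not the SD, is the primitive being encoded. Validation data
enter *only* through the Beta priors; a joint case-control/validation
likelihood is out of scope.

Two structural choices matter:

* **Identifiability**: the posterior is zero (log-density `-Inf`) outside
  `Se_g + Sp_g > 1`. This removes the mirror mode of misclassification
  models; the elicited priors put negligible mass there anyway.
* **Sampler**: component-blocked adaptive random-walk Metropolis —
  `(logit p0, theta)` jointly, each `Se`/`Sp` separately on the logit
  scale, with Jacobian terms for the transforms. Step sizes adapt toward
  acceptance rates 0.35 (2-D block) / 0.44 (scalar blocks) during burn-in
  only, so the post-burn-in kernel is a fixed, valid Metropolis kernel.
  Any correct sampler targeting this posterior would do; correctness here
  is established against a 2-D quadrature oracle (misclassification
  parameters fixed), against prior recovery on a zero-count table, and by
  credible-interval calibration over replicates with truth drawn from the
  priors (all in the test suite).

Defaults (4 chains, 50 000 iterations, 10 000 burn-in) finish desk-scale
problems in well under a minute; the tests and examples use smaller,
stated sizes. `diagnostics()` reports split-Rhat and a multi-chain
effective sample size (Geyer initial-monotone truncation); a run is
flagged non-converged if any Rhat exceeds 1.01. `summary()` pools chains
and reports mean and 2.5/50/97.5 percentiles for the OR (summarized as
`exp(theta)` draw by draw, so the reported mean is the posterior mean of
the OR itself), the four misclassification parameters and both
prevalences.

## What the synthetic generator emulates — and what it does not

`synthetic_truth()` + `generate_study()` + `generate_validation()` emulate
the motivating design: a case-control study with fixed margins, binary
true exposure (`p0 = 0.15` in controls by default, true OR 1), per-subject
independent misclassification at `Se`/`Sp` set to the elicited prior means
(cases 0.850/0.822, controls 0.805/0.836), and validation subsamples of
225 cases / 1800 controls mirroring the bundled validation study's size.
The default main-study size is 4000 per arm: the published fixed-value CI
of 0.95–1.16 implies a Woolf log-width of about 0.20, which at an apparent
exposure proportion of ~0.26 corresponds to roughly 4000 subjects per arm;
since the source study's own 2x2 table is not public, that width-matched
scale is the package's stand-in.

Real data the generator does **not** emulate: correlated reporting within
subjects or worksites, time-varying exposure, selection bias, and
validation subsamples that are not simple random draws. Passing
parameter-recovery and calibration tests therefore demonstrates internal
consistency of model + generator, not robustness to those violations.

## Numerical choices and edge cases

* Percentiles everywhere: linear interpolation between order statistics.
* `correct_counts()` accepts real-valued cells, so expected (non-integer)
  tables round-trip exactly: forward misclassification followed by
  correction reproduces the input to machine precision whenever
  `Se + Sp > 1`.
* A zero-margin study table is accepted by the model (`M = 0` contributes
  nothing to the likelihood), which is how priors-only runs are expressed;
  operations that need a margin (correction, crude OR) check it themselves.
* MCMC starting points: misclassification parameters at prior means
  (jittered on the logit scale), `p0` back-solved from the apparent
  control proportion through the prevalence identity, `theta` near 0; up
  to 100 redraws if a start lands outside the identifiability region.
* Case-control label swap: exchanging the two strata (and their priors)
  negates the posterior of `theta` only approximately — exactness would
  require a logit-flat prevalence prior, while the uniform `p0` prior
  introduces a small O(1/n) asymmetry (~0.01 on the log-OR scale at the
  test's settings, measured by quadrature).
* Kernel densities for overlay figures (`density_export()`): Gaussian
  kernel with Silverman's-rule bandwidth on the log-OR scale, transformed
  back so the density integrates to 1 over the OR axis.

## Reproducing published-scale results

The pipeline (`run_pipeline()`) chains prior elicitation, fixed
correction at prior means, PBA and the Bayesian model on one table, and
`check_interval_ordering()` implements the external-reproduction recipe:
given a user-supplied source-study 2x2 table (which this package cannot
ship), it verifies the qualitative pattern expected when misclassification
uncertainty dominates — the Bayesian credible interval wider on the log
scale than the PBA simulation interval, both wider than the fixed-value
CI. On the width-matched synthetic surrogate the test suite confirms
exactly that ordering. The headline posterior numbers of the motivating
analysis are *not* asserted anywhere, because recomputing them requires
the unpublished source table.

```{r, eval = FALSE}
study <- read_table_csv("source_study_2x2.csv") # user-supplied
res <- run_pipeline(study, validation = nightshift_validation(), seed = 1)
res$comparison
check_interval_ordering(res)
```

## Known limitations

* Summary-level only: no record-level bias analysis, no covariates,
  no matching, no outcome misclassification, no selection bias.
* The fixed-value CI convention (Woolf on corrected counts) matches the
  spreadsheet tools this workflow is meant to audit; other variance
  estimators for corrected tables exist and would change that one column.
* The Metropolis sampler is tuned for 2x2 problems; very extreme tables
  (apparent proportions at the false-positive floor) concentrate the
  posterior near the boundary and may need longer runs — watch
  `diagnostics()`.
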
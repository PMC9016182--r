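---
title: "Methods: high-dimensional DNA methylation mediation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: high-dimensional DNA methylation mediation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hdmethmediate)
```

## The scientific problem

A binary exposure (current smoking) is associated with a binary disease
outcome (Crohn's disease in the motivating application). DNA methylation at
CpG sites is both responsive to smoking and associated with immune-mediated
disease, so individual CpGs are natural candidate *mediators*: part of the
exposure effect may act through exposure-induced methylation changes. The
difficulty is scale — a 450K-style array leaves hundreds of thousands of
candidate mediators after quality control, while a typical case-control
cohort has a few hundred subjects — and confounding: blood methylation
profiles are dominated by leukocyte composition, which differs between cases
and controls, so cell-type proportions (together with age and sex) must be
adjusted for in every model.

The assumed causal structure is: confounders $C$ (age, sex, six leukocyte
proportions) affect exposure-outcome-mediator relations; exposure $X$
affects mediators $M_1,\dots,M_P$ and, directly, the outcome $Y$; each
mediator may affect $Y$. All mediator analysis is per-CpG (causally
unrelated mediators); no exposure-mediator interaction enters the outcome
model.

## The three-stage procedure

Given a cohort ($Y$, $X$, $C$) and a standardized M-value matrix, `hdmm()`
runs:

**1. Sure independence screening.** For each probe $j$ the single-mediator
logistic outcome model $Y \sim X + M_j + C$ is fitted and the mediator
coefficient recorded as $\omega_j$. The $d = \lceil 2n/\ln n\rceil$ probes
with the largest $|\omega_j|$ are retained (99 at $n = 277$). The screening
statistic is confounder-adjusted rather than a raw correlation; a
marginal-correlation variant is available behind a flag. The source
publications leave $\omega$ undefined; the adjusted outcome-model
coefficient is the convention of high-dimensional mediation screening and is
consistent with the confounding arrows of the causal diagram. The ceiling
(rather than floor or round) reproduces the published count:
$2\cdot 277/\ln 277 = 98.5 \to 99$.

**2. De-sparsified LASSO selection.** On the screened design
$[X, M_{(1)},\dots,M_{(d)}, C]$ the logistic LASSO
$\hat\beta = \arg\min\, P_n\rho_\beta + \lambda\lVert\beta_{\text{pen}}\rVert_1$
is fitted with only the mediators penalized — the intercept, exposure and
confounders are forced into the model, mirroring fully adjusted analyses.
With $\hat\Sigma = P_n\ddot\rho_{\hat\beta}$ (the average observed
information) and $\hat\Theta$ a nodewise-LASSO relaxed inverse of
$\hat\Sigma$, the de-sparsified estimator is
$\hat b = \hat\beta - \hat\Theta\, P_n\dot\rho_{\hat\beta}$, asymptotically
normal with standard errors
$\sqrt{(\hat\Theta\hat\Sigma\hat\Theta^\top)_{jj}/n}$. Two-sided normal
p-values over the mediator coefficients are Benjamini-Hochberg adjusted and
candidates selected at FDR $q = 0.05$ (strict inequality).

**3. Counterfactual mediation per candidate.** For each selected CpG the
linear mediator model $E[M\,|\,x,c] = \beta_0 + \beta_1 x + c^\top\beta_c$
and the logistic outcome model
$\operatorname{logit} P(Y=1\,|\,x,m,c) = \theta_0 + \theta_1 x + \theta_2 m + c^\top\theta_c$
are fitted. On the odds-ratio scale the effects are the exact products
$\log OR_{ACME} = \beta_1\theta_2$ and $\log OR_{ADE} = \theta_1$. On the
risk-difference scale, potential probabilities
$\bar P(t,t') = \tfrac1n\sum_i E_\varepsilon\, \hat P\{Y=1 \mid X=t,
M = \hat\mu(t',C_i)+\varepsilon, C_i\}$ are computed by integrating the
fitted normal mediator distribution through the outcome model, and

$$\mathrm{ACME} = \tfrac12\sum_{t\in\{0,1\}} \bar P(t,1)-\bar P(t,0), \qquad
  \mathrm{ADE} = \tfrac12\sum_{t'\in\{0,1\}} \bar P(1,t')-\bar P(0,t').$$

With this arm-averaged definition the total effect
$\bar P(1,1)-\bar P(0,0)$ decomposes *exactly* as ACME + ADE, even for the
noncollapsible logistic model. Confidence intervals and p-values come from a
nonparametric bootstrap over subjects (percentile intervals; the p-value is
twice the crossing proportion, floored at $1/n_{\text{boot}}$).

## Sensitivity analysis in $\rho$

Identification of the ACME rests on sequential ignorability. Its violation
is parameterized by $\rho$, the correlation between the mediator-model
residual and the latent error of a probit outcome model. The probit link is
used here because the correlated-error construction needs a latent-Gaussian
outcome; the probit baseline at $\rho = 0$ is reported next to the primary
logit estimate so the (small) link discrepancy is visible rather than
hidden.

Writing the observed probit fit as $\tilde\theta$ and the mediator-model
residual SD as $\sigma$, the structural coefficients consistent with
residual correlation $\rho$ are recovered in closed form,
$$\theta_2 = \tilde\theta_2\sqrt{1-\rho^2} - \rho/\sigma,\qquad
  \theta_k = \tilde\theta_k\sqrt{1-\rho^2} + \rho\,\beta_k/\sigma,$$
and the ACME recomputed analytically with the mediator integrated out
(latent scale $\sqrt{\theta_2^2\sigma^2 + 2\theta_2\rho\sigma + 1}$). The
curve $\mathrm{ACME}(\rho)$ is monotone for fixed fits, so its zero crossing
is unique; the reported $\rho_0$ is the grid point (default grid $-0.9$ to
$0.9$ in steps of $0.1$, the published reporting granularity) nearest the
crossing, or flagged absent. A $\rho_0$ near zero means a small
unmeasured-confounding correlation would suffice to explain the estimated
mediation away.

## What the synthetic cohort generator emulates

`simulate_cohort()` produces the statistical structure the analysis assumes:
Dirichlet cell-type proportions (means set to the published control-group
composition), age and sex, mediator M-values with confounder loadings and
exposure effects `alpha_xm` on the true mediator CpGs, a logistic outcome in
$X$, the true mediators and confounders, beta-scale storage with simulated
detection p-values and annotation, and an embedded cell-type reference whose
marker probes are mixed by each subject's true proportions so deconvolution
is exercised end to end. The truth record carries the closed-form
$\log OR_{ACME} = \alpha_j\theta_{2j}$ per true mediator.

Design choices worth knowing:

* **Prospective generation.** Exposure is Bernoulli with the marginal
  prevalence implied by the configured case/control prevalences, and the
  outcome intercept is calibrated by root-finding so the *expected* case
  fraction matches the configured 103:174 split. A retrospective design that
  fixes case counts exactly and draws exposure per group cannot also satisfy
  a stated outcome model, so the prospective route was chosen; realized
  counts are binomial around the target, and realized exposure-by-group
  prevalences follow from the configured effects rather than being imposed.
* **Effect defaults are the published estimates** for the four significant
  CpGs (exposure->CpG effects around $-0.1$; CpG->outcome log-odds between
  $-2$ and $-4.5$ per standardized M unit). These are large outcome effects:
  the simulated latent scale is wide and the marginal exposure-outcome odds
  ratio attenuates accordingly — which is faithful to the published effect
  sizes, not a bug. Mediator noise is Gaussian on the M-value scale
  (`noise_sd = 1`) because the analysis scale is M; `confounder_strength`
  (default 1) scales both the mediator loadings and the confounder terms of
  the outcome model, with a positive granulocyte coefficient so cases run
  granulocyte-high as in the published cohort. An optional block-correlation
  knob (`block_rho`) adds within-block noise correlation; no claim is made
  that any particular value is realistic.
* **Desk scale.** The default `n_probes = 2000` keeps a full pipeline run
  under a minute; the generator scales to array-sized matrices if asked.
* Cell proportions from the generator lie exactly on the simplex, which
  would make a regression design with an intercept and all six proportions
  singular. The analysis path therefore adjusts for *estimated* proportions
  (`analysis_cohort()`, unnormalized NNLS deconvolution) — exactly what a
  real study does — and the fitting functions treat exact collinearity as an
  error rather than silently dropping columns.

What passing tests on these cohorts do **not** show: realistic
mediator-mediator correlation (CpGs are near-independent by default),
probe-type chemistry artifacts, batch effects, or missingness (missing
values are an error by design). Calibration results transfer to real arrays
only to the extent those features do not dominate.

## Preprocessing contracts

Filters run in a fixed order — samples (mean detection $p > 0.05$, strict),
probes (any retained sample with detection $p \ge 0.01$; a conservative
any-sample reading, since no sample-fraction rule is published), annotation
(SNP-overlap, then chrX/chrY, a both-flagged probe counted under the SNP
rule) — followed by across-sample quantile normalization
(`limma::normalizeQuantiles`; plain quantile matching, not control-probe
regression, since matrix-level input carries no control probes), the
M-value transform $\log_2 b/(1-b)$ with clipping at `eps = 1e-6`, and
per-probe standardization (constant probes dropped with a warning).
Deconvolution is a single-step non-negative least squares projection on the
reference profiles, reported unnormalized (sums may fall below 1) with a
normalized variant alongside.

## Numerical choices

* LASSO solutions come from coordinate descent (`glmnet`) with penalty
  factors rescaled so the objective is exactly
  $P_n\rho + \lambda\lVert\beta_{\text{pen}}\rVert_1$; KKT conditions are
  verified at the solution ($|score_j| \le \lambda + 10^{-6}$ on the zero
  set). $\lambda = 0$ and $\lambda \ge \lambda_{\max}$ short-circuit to the
  exact solutions.
* $\lambda$ is selected by 10-fold cross-validated deviance on a 50-point
  log-spaced path from $\lambda_{\max}$, spanning four decades when
  $n > 5p$ and two otherwise — the near-unpenalized end of a longer path is
  a separation regime for $p$ near $n$ that costs heavily and never wins CV.
  Folds are seeded.
* Nodewise penalties are tied across nodes: the nodewise regression is
  cross-validated on five representative columns, the selected penalties are
  reduced to the median rate $\lambda_k/\sqrt{\hat\Sigma_{kk}}$, and every
  node gets that rate times its own $\sqrt{\hat\Sigma_{jj}}$. One
  cross-validation per column (d + 10 of them per fit) costs an order of
  magnitude more wall time and changed nothing detectable in calibration at
  these sizes; explicit per-node penalties can still be supplied.
* The mediator integral uses 1,000 shared (common-random-number) normal
  draws by default; sharing the draws across bootstrap replicates removes
  Monte-Carlo jitter from the bootstrap distribution. The probit path
  integrates the mediator analytically, which is what makes the
  $\rho = 0$ sensitivity identity exact.
* Bootstrap replicates that fail to converge are dropped and counted; more
  than 10% dropped is an error. Default 1,000 resamples (configurable; the
  published analysis quotes far more, which only narrows the Monte-Carlo
  error of the interval endpoints).
* Ties in screening are broken by ascending probe index; the retained set is
  reported in decreasing $|\omega|$ order.

## Simulation sizes used by the test suite

The packaged checks run, among others: a 200-replicate global-null study at
the study scale ($n = 277$, 99 probes so screening retains everything —
screening the same data it tests would make post-selection p-values
non-uniform by construction, a property of every screen-then-test pipeline);
per-probe Kolmogorov-Smirnov uniformity of the de-sparsified p-values and
the Benjamini-Hochberg false-selection budget; odds-ratio-scale effect
recovery at $n = 5000$ under a rare outcome; 100-replicate bootstrap
coverage of the ACME at $n = 300$ with 500 resamples; and byte-identical
reruns of the full file-based pipeline at $p = 2000$. Fold counts and
Monte-Carlo draw counts in these studies are reduced from interactive
defaults (5 CV folds, 60-200 draws) so the whole suite completes on a
single CPU in well under half an hour; all are recorded in the test code.

## Known limitations

* Post-selection inference: candidate CpGs are selected and then their
  mediation effects estimated on the same data, as in the source analysis;
  the mediation p-values are conditional on selection and should be read as
  descriptive.
* Per-CpG mediation ignores mediator-mediator correlation; jointly mediating
  sets are out of scope.
* The sensitivity analysis assumes the latent-Gaussian (probit) outcome
  formulation and fixed fitted parameters along the curve.
* The preprocessing is matrix-level only: no IDAT parsing, no control-probe
  normalization, no batch correction, no imputation.
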
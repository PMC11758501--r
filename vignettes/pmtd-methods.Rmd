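---
title: "Personalized-MTD dose-finding designs: models, priors and simulation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized-MTD dose-finding designs: models, priors and simulation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pmtddesign)
```

## 1. Setting and model

A Phase I trial enrolls patients sequentially in small cohorts on an
ordered dose grid $\mathcal{D} = (d_1, \dots, d_K)$ and observes a binary
dose-limiting toxicity (DLT) outcome $y_i$. The estimand is not a single
maximum tolerated dose but the *personalized* MTD (pMTD): the dose whose
DLT probability, given a patient's covariates, is closest to the target
rate $\tau$.

All designs in this package share the logistic dose-toxicity model

$$\operatorname{logit} p_T(d_k \mid x_i) \;=\; \alpha + \beta
\log(d_k/d_r) + \textstyle\sum_{j=1}^p \gamma_j x_{ij}, \qquad \beta > 0,$$

with reference dose $d_r$ and a bivariate normal prior on
$(\alpha, \log\beta)$. The likelihood is the product of Bernoulli terms
over enrolled patients; the posterior mean
$\hat p_T(d_k \mid x) = \mathbb{E}[\,p_T(d_k \mid x)\mid D_n\,]$ — the
mean of the probability, not the plug-in at posterior-mean parameters —
drives allocation:

$$k^\ast(x) = \arg\min_k \lvert \hat p_T(d_k \mid x) - \tau\rvert,$$

ties resolved to the **highest** dose index. The same tie rule defines the
true pMTD, so estimated and true quantities are always comparable. No
dose-skipping restriction is imposed (the allocation rule is used as
stated); a `no_skip` flag is available for practical use but off by
default.

## 2. The design family

* **BLRM** (`design_spec("blrm")`) — covariate-free reference design; one
  shared dose per cohort.
* **BLRMc** — covariates always in the model with flat
  $\gamma_j \sim N(0, 4)$, matching the variance given to the dose
  coefficients; patients are allocated individually to their estimated
  pMTD.
* **cchange** — the trial starts covariate-free but stores covariates from
  enrollment. After every cohort, for each candidate covariate $j$ not yet
  included, both the current working model and the working model plus $j$
  are refitted to all $n$ patients, and
  $\mathcal{R}_j = n^{-1}\sum_i 1\{d^{(\text{without})}_{(i,n)} \ne
  d^{(\text{with})}_{(i,n)}\}$ is the fraction of patients whose
  recommended dose changes. If $\mathcal{R}_j$ strictly exceeds its
  threshold, covariate $j$ enters the model permanently (inclusion is
  never reversed, so the included set is monotone over cohorts). The
  comparison baseline is the model *actually in use*, i.e. with two
  candidates the "with" model adds $j$ to the currently included set.
* **Bayesian LASSO** — $\gamma_j \mid \lambda_g \sim
  \text{Laplace}(0, \lambda_g)$ with density
  $(\lambda/2)e^{-\lambda|\gamma|}$ (rate parameterization, scale
  $1/\lambda$), one rate per covariate *group* (continuous, binary), and
  hyperprior $\lambda_g \sim \text{InvGamma}(\delta_g, \delta_g)$. Smaller
  $\delta$ penalizes harder.
* **Spike-and-Slab** — $\gamma_j \mid m_j \sim (1-m_j)f_1 + m_j f_0$ with
  spike $f_1 = N(0, \nu_j)$, slab $f_0 = N(0, 4)$ and
  $m_j \sim \text{Beta}(2,2)$. The weight $(1-m_j)$ multiplies the
  lower-variance spike, exactly as the model is written; because that
  labelling is ambiguous in prose, `prior_spec(swap_components = TRUE)`
  exposes the alternative reading as a documented switch.

### Calibrated hyperparameter defaults

These defaults are the values selected by the original grid calibration of
the design family (geometric mean of correct pMTD allocations across
scenarios) and are reproduced here as constants, re-derivable with
`calibrate_hyperparameter()`:

| parameter | two normal covariates | normal + binary |
|---|---|---|
| cchange threshold | 0.2 | 0.1 (normal), 0.3 (binary) |
| LASSO $\delta$ | 0.4 | 1 (normal), 0.4 (binary) |
| spike variance $\nu$ | 0.05 | 0.1 (normal), 0.05 (binary) |

Base prior: mean $(\operatorname{logit} 0.1,\, 0)$, covariance
$\mathrm{diag}(4, 4)$ — its implied prior *median* toxicity at the
reference dose is exactly 0.1 (a unit test asserts this). Slab variance 4;
$m_j \sim$ Beta(2, 2).

## 3. Posterior computation

The original study used Stan; this package ships two self-contained
engines behind one interface, which also gives an internal cross-check
that an external sampler cannot:

* **Grid quadrature** (`engine = "quadrature"`): dense tensor grid over
  $(\alpha, \log\beta)$ (default $201^2$ nodes spanning $\pm 6$ prior SDs;
  $61^3$ when one flat-normal covariate is added). For the covariate-free
  model the likelihood depends on the data only through per-dose DLT
  counts, so thousands of refits per simulation reuse one precomputed
  probability table — this is what makes the 10 000-fit benchmark runs
  take about a minute.
* **Adaptive random-walk Metropolis MCMC** (`engine = "mcmc"`, compiled
  C++): component-wise proposals with Robbins–Monro scale adaptation
  during warmup (target acceptance 0.44), LASSO rates sampled as
  $\log\lambda_g$ and mixture weights as $\operatorname{logit} m_j$ with
  the appropriate Jacobians. Defaults (the study does not state its MCMC
  configuration, so these are package choices): 4 chains, 1000 warmup +
  1000 kept draws each, split-$\hat R$ and acceptance rate recorded;
  fits are flagged, not dropped, when $\hat R \ge 1.1$. The sampler uses
  R's RNG stream, so a single `seed` reproduces a fit bit-for-bit.

Numerical guards: Bernoulli probabilities are clamped at $10^{-12}$ before
taking logs; the quadrature normalizer subtracts the maximum log-posterior
before exponentiating. The test suite requires the two engines to agree
within 0.01 on posterior-mean curves for two-parameter fits.

## 4. The simulated world

`scenario_truth` objects state the data-generating process. The benchmark
grid is $(1, 3, 5, 7, 9)$ mg with $d_r = 5$ mg and $\tau = 0.25$; trials
enroll $N = 30$ patients in cohorts of 3, the first cohort at the lowest
dose. Five scenarios place the MTD at each dose in turn, defined by their
per-dose toxicity probabilities.

**Closed-form scenario recovery.** Because each benchmark row was
generated by an exact two-parameter logistic model, `calibrate_truth`
recovers $(\alpha, \beta)$ in closed form from two anchor cells — the
target-rate dose and its upper neighbour — and the recovered model
reproduces the remaining cells of rows 1 and 3 at printed precision
(an acceptance test). Rows 2, 4 and 5 contain single cells that are *not*
consistent with their anchor pair at printed rounding; the bundled fixture
stores the anchor-implied values there so every row is exactly one model.

**Covariates.** Continuous covariates are standard normal (the package
accepts means/SDs so real covariates can be centered and standardized);
binary covariates are Bernoulli(0.5); correlated continuous blocks are
multivariate normal with a user correlation matrix. With covariates, the
scenario table is matched in the *marginal* (covariate-averaged) toxicity
probability $p_T(d) = \int p_T(d\mid x)\, q(x)\,dx$, computed by
Gauss–Hermite quadrature (exact enumeration for binary covariates, Monte
Carlo as a cross-check). $\gamma$ is held fixed during calibration — the
system is underdetermined otherwise — and the dose coefficients are found
by least squares on the logit scale.

**Choice of the covariate effect.** The generating coefficients of the
original covariate scenarios are available only in supplementary data that
is not redistributed here. The package's stated default is
$\gamma_j = 1.5$ per significant covariate, chosen once so that (i) the
population pMTD distribution in scenario 1 is strongly dispersed with the
lowest dose modal and substantial mass at the top dose — the qualitative
shape of the published example — and (ii) the marginal calibration
residual stays below 0.07 on the probability scale in all scenarios
(γ = 2 per covariate makes scenario 1's flat marginal curve unmatchable;
the calibration tolerance is an RMS logit residual of 0.25). Users with
the supplementary coefficient file can load it via
`read_supplementary_coeffs()` and reproduce those scenarios exactly.

**What a green test does not establish.** The generator draws i.i.d.
patients with instantly observed binary outcomes from the same parametric
family the designs fit (except in the Emax sensitivity runs). Real trials
have accrual dynamics, delayed toxicities, measurement error in
covariates, and dose–covariate interactions — none of which are simulated
— so passing operating-characteristic checks certifies the *statistical
machinery*, not clinical performance.

## 5. Operating characteristics

Per trial, four metrics: `mtd_trial` / `ov_trial` — percent of enrolled
patients allocated their true pMTD / a dose strictly above it; `mtd_add` /
`ov_add` — the same for 100 fresh patients drawn from $q(x)$ and
recommended a dose by the trial's *final* model (for the cchange design,
whatever model was in use at trial end — with covariates only if inclusion
had occurred; this reading is a package decision, flagged as such).
"Overdose" means strictly above the patient's own pMTD, which makes
overdosing structurally impossible when the MTD is the top dose — the
suite asserts that zero exactly.

Aggregation: within a scenario, trials are averaged arithmetically (a
geometric mean over trials would be annihilated by any single 0%-correct
trial, and per-trial values are exactly 0 or 100 in no-covariate
scenarios); across scenarios, the summary uses the geometric mean for the
MTD metrics and the arithmetic mean for overdosing. The printed reference
row (70, 80, 78, 49, 83 → 71; 30, 14, 12, 20, 0 → 15) is an exact test of
this arithmetic. Internally values keep full precision; tables round to
integers for display. Averaging precedes rounding.

Replication: the full-fidelity setting is 1000 trials per scenario;
the documented desk-scale mode used by the tests and the acceptance script
is 200 (covariate-free, quadrature) and 30–100 with reduced MCMC draws
(2 chains × 500+500) for covariate designs. Per-trial seeds derive
deterministically from one master seed, so results are independent of
evaluation order; within `run_trial`, the patient-generation RNG stream is
deliberately isolated from the model-fitting stream so that two designs
sharing a seed face identical patients whenever their allocations agree —
this is what makes the "cchange with an unreachable threshold equals the
BLRM path" property testable bit-for-bit.

## 6. Design choices in open territory

* **Inclusion statistic over all $n$ patients.** The criterion's prose
  mentions consecutive cohorts while its formula sums over all enrolled
  patients; the all-patients sum is implemented (the formula is explicit).
* **Strict threshold comparison** (`>`), evaluated after every cohort from
  the first; thresholds outside $(0,1)$ are deliberately allowed — 0
  forces inclusion at the first disagreement, values above 1 disable
  inclusion, both used as test boundaries.
* **Tie-break upward** for the closest-to-target dose, applied uniformly
  to true and estimated pMTDs.
* **Per-trial arithmetic averaging** of MTD metrics (see §5).
* **Lasso/spike-slab reduction checks.** With the spike variance raised to
  the slab's, the spike-and-slab fit must reproduce the flat-normal fit
  (tested); the analogous LASSO reduction has no exact finite
  counterpart — its rate is random under the hyperprior — so the LASSO is
  validated directionally at the operating-characteristics level instead.

## 7. Known limitations

* Single-agent escalation only; combination partners enter as covariates.
* No covariate interactions, no time-to-event outcomes, no
  safety-stopping rules, no efficacy endpoint, no placebo arm.
* Covariate exclusion after inclusion is intentionally impossible in the
  cchange design.
* Grid quadrature covers at most one extra covariate coefficient; larger
  models rely on the Metropolis sampler, whose defaults are tuned for
  $p \le 2$ covariates and $N \le 300$; heavier models deserve a
  gradient-based sampler.
* The Emax family is provided for generating misspecified truths (and as
  a fit family for scenario calibration), not as a fitting model for the
  designs — matching its role in the sensitivity analyses.
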
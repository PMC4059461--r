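---
title: "Truncated concordance for competing-risks prognostic models"
author: "crcindex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Truncated concordance for competing-risks prognostic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcindex)
```

## The discrimination problem

A prognostic model for an event of interest (say, coronary heart disease)
is useful when it ranks subjects correctly by their absolute risk of that
event. When competing events (say, non-CHD death) can preclude the event of
interest, the absolute risk is the cause-specific cumulative incidence
$F_1(t \mid X) = P(T \le t, D = 1 \mid X)$, and discrimination must be
judged against it — not against the latent time-to-event of a
single-failure-type analysis.

`crcindex` implements the truncated cause-specific concordance index

$$\mathcal C_1(t) = P\big(M(t, X_i) > M(t, X_j) \mid D_i = 1,\ T_i \le t,\
(T_i < T_j \text{ or } D_j = 2)\big),$$

the probability that, of a random comparable pair, the subject who
experiences the event of interest earlier (or while the partner experiences
a competing event) carries the higher predicted risk $M(t, X)$. A pair is
comparable when subject $i$ has the event of interest by the horizon $t$
and subject $j$ either fails later or has a competing event: under the
"treatment that prevents only the event of interest" reading, $i$ is then
unambiguously in greater need. Pairs where both subjects have competing
events carry no ranking information and are excluded. $\mathcal C_1(t)$
depends on $F_1$ and the marker distribution only — a property that makes
it the right summary when the model targets the absolute risk of cause 1.

An alternative index restricting comparability to $T_i < T_j$ (both-causes
controls excluded) also exists in the literature; it depends on $F_2$ as
well and is not estimated here.

Truncation at $t$ is not a defect: with follow-up limited to the study
horizon, no censoring-robust estimate of the unrestricted concordance
exists, and $t$ is part of the estimand's interpretation.

## Estimators

With right-censoring we observe $\tilde T_i = \min(T_i, C_i)$ and
$\tilde D_i = \Delta_i D_i$ (0 = censored). Writing
$\tilde A_{ij} = 1\{\tilde T_i < \tilde T_j\}$,
$\tilde B_{ij} = 1\{\tilde T_i \ge \tilde T_j, \tilde D_j = 2\}$,
$\tilde N^1_i(t) = 1\{\tilde T_i \le t, \tilde D_i = 1\}$ and
$Q^{ij}(t) = 1\{M(t,X_i) > M(t,X_j)\}$:

* **Naive (Harrell-type)** — `concordance_naive()`: the proportion of
  concordant pairs among pairs whose ordering is decidable from the
  observed data,
  $\sum_{ij} (\tilde A_{ij} + \tilde B_{ij}) Q^{ij} \tilde N^1_i \big/
   \sum_{ij} (\tilde A_{ij} + \tilde B_{ij}) \tilde N^1_i$.
  Ignoring the non-evaluable pairs makes it asymptotically biased upward
  under censoring (early, easy-to-rank pairs are over-represented).
* **IPCW** — `concordance_ipcw()`: each evaluable pair is reweighted by the
  inverse of its probability of being evaluable under a working model
  $\hat G(t \mid x)$ for the censoring survival $P(C > t \mid x)$:
  $\hat W_{ij,1} = \hat G(\tilde T_i- \mid X_i)\hat G(\tilde T_i \mid X_j)$
  for pairs evaluable through $i$'s earlier failure and
  $\hat W_{ij,2} = \hat G(\tilde T_i- \mid X_i)\hat G(\tilde T_j- \mid X_j)$
  for pairs evaluable through $j$'s competing event. The weighted ratio is
  consistent and asymptotically normal whenever the working model is
  correctly specified. The asymmetry between the right limit in
  $\hat W_{ij,1}$ and the left limit in $\hat W_{ij,2}$ is implemented
  exactly as defined.
* **Exact definition** — `concordance_exact_uncensored()`: the plain pair
  count on uncensored data; the oracle all estimators collapse to when no
  one is censored.

Two working models are provided (`fit_reverse_km()`, `fit_cox_censoring()`):
the marginal reverse Kaplan–Meier estimate (valid under censoring
independent of everything) and a Cox proportional-hazards model for the
censoring hazard with Breslow baseline (valid under covariate-dependent
censoring, conditionally independent given covariates). All step functions
are right-continuous and evaluable at left limits, matching
$G(t-\mid x) = P(C \ge t \mid x)$.

`timedep_auc()` computes the companion cumulative case/control AUC at a
fixed horizon with either event-free controls or event-free-plus-competing
controls; with incident cases, the concordance is exactly the
control-count-weighted average of the AUC over cause-1 event times, an
identity the test suite checks to $10^{-12}$.

### Ties, causes, degenerate inputs

Prediction ties count zero in the numerator under the default
`tie_handling = "strict"` (the index as defined) and one half under
`"half_weight"`. Ties in observed times need no special rule: the
definitions' strict/non-strict inequalities decide every pair, and two
cause-1 events at the same instant are non-comparable in both directions —
the formulas are followed literally. Cause 2 is analysed by relabelling
the two causes (`cause = 2`); event codes above 2 are rejected rather than
merged silently. A horizon with no evaluable pairs raises a classed
error rather than returning `NaN`.

Positivity deserves a note. The theory assumes $G(\tau \mid x) > \epsilon$
beyond the horizon. In finite samples $\hat G$ can reach zero before $t$
(heavy censoring, last observation censored), yet the estimator only
evaluates $\hat G$ at observed case times, where the product-limit form
keeps it positive; the estimator is therefore defined whenever those
weights are positive, and a zero weight on an evaluable pair raises a
positivity error. Separately, a configurable floor (`weight_floor`,
default 0.01) warns when any used weight falls below it and can truncate
weights at the floor (`truncate_weights = TRUE`) for stability diagnostics
at high censoring rates.

## Inference

* `asymptotic_se_km()` — for the marginal-KM IPCW estimator, a plug-in
  estimate of the asymptotic variance from the estimated influence
  function, assembled from first principles in two parts: the projection of
  the order-2 V-statistic pair sums, and the propagation of the estimated
  Kaplan–Meier weights through the standard martingale representation of
  the product-limit estimator,
  $\mathrm{IF}_G(t; k) = -G(t)\big[\tfrac{1\{\tilde T_k \le t, \tilde D_k = 0\}}{H(\tilde T_k)}
  - \int_0^{t \wedge \tilde T_k} \tfrac{d\Lambda_c(u)}{H(u)}\big]$,
  with $H(u) = P(\tilde T \ge u)$. Only products of the influence matrices
  with fixed vectors are needed, which reduce to sorted prefix sums, so the
  computation stays $O(n^2)$ overall and no $n \times n$ influence matrix
  is formed. The implementation is validated against an exact leave-one-out
  jackknife (agreement within a few percent at $n$ of a few hundred, both
  censored and uncensored) and against the empirical sd of the estimator
  across simulation replications. Wald intervals are clipped to $[0, 1]$.
  Cox-weighted and naive estimators are refused — their weight-estimation
  variability is not covered by this formula — and directed to the
  bootstrap.
* `bootstrap_ci()` — percentile bootstrap resampling subjects (never
  pairs), refitting the censoring working model inside every resample so
  its variability propagates. Degenerate resamples (no evaluable pairs) are
  redrawn up to a cap of 100 and counted. Deterministic given `seed`.

## The simulation engine and what it emulates

`sim_scenario()` encodes the cause-specific Cox-exponential generator:
$X \sim N(0,1)$, latent times
$T_1 \sim \mathrm{Exp}(\lambda_{01} e^{\beta_1 X})$,
$T_2 \sim \mathrm{Exp}(\lambda_{02} e^{\beta_2 X})$, $T = \min(T_1, T_2)$,
and censoring $C \sim \mathrm{Exp}(\lambda_{0,\mathrm{cens}} e^{\gamma_1 X})$.
The shipped presets are the two study conditions: CR1
($\lambda_{01}=1, \lambda_{02}=2, \beta_1=\beta_2=1$; true
$\mathcal C_1(q_{75}) = 0.621$) and CR2
($\lambda_{01}=1, \lambda_{02}=0.5, \beta_1=2, \beta_2=-1$; true
$\mathcal C_1(q_{75}) = 0.850$), evaluated with the marker itself as
prediction, $M(t, X) = X$, at the 75% (or 50%) quantile of the marginal
distribution of $T$.

This generator emulates proportional cause-specific hazards with a single
Gaussian marker, constant baselines and exponential censoring. It does not
emulate time-varying effects, non-exponential baselines, tied or discrete
event times, covariate-dependent censoring beyond one log-linear term, or
model-based predictions estimated with error (the marker is the truth's
own ordering). Tests passing under it therefore certify the estimators'
behaviour under a correctly specified, smooth, continuous-time world — not
robustness to misspecification beyond the covariate-dependent-censoring
cells.

Supporting operations:

* `calibrate_censoring_rate()` bisects on $\log \lambda_{0,\mathrm{cens}}$
  until the Monte Carlo estimate of $P(\tilde D = 0 \mid \tilde T < t)$ —
  the censored fraction among observations before $t$, the study's
  definition — hits the target within 0.005 (default MC size 200000,
  common random numbers across bisection steps so the objective is
  monotone). A Gauss–Hermite quadrature route serves as a cross-check.
* `marginal_quantile()` solves $P(T \le t) = p$ by Gauss–Hermite
  integration of $E_X e^{-(\lambda_1(X) + \lambda_2(X)) t}$ plus
  root-finding (or empirically by MC).
* `true_concordance()` computes the estimand itself. The Monte Carlo route
  applies the exact pair count to an uncensored sample of 100000. The
  quadrature route uses the closed-form inner integral
  $\int_0^t (1 - F_1(s \mid x_j))\, dF_1(s \mid x_i)$ and integrates the
  pair expectation on the probability scale $(\Phi(x_i), \Phi(x_j))$, the
  numerator over the triangle where the ordering indicator equals 1.
  The triangle decomposition matters: a tensor rule that straddles the
  indicator's discontinuity (e.g. 2-D Gauss–Hermite in $x$) converges only
  at rate $O(1/N)$ and is still 0.003 low for CR2 at order 256, while the
  triangle rule agrees with itself to $10^{-6}$ between orders 150 and 250
  and with the large-sample MC value within Monte Carlo error.

Randomness follows a counter-based seed-derivation scheme
(`derive_seed()`): every replication, and within it the marker, the two
latent event times and the censoring draw, uses its own derived substream,
so components are independently reproducible and adding study cells never
perturbs existing ones.

## The study runner and problem sizes

`run_cell()`/`run_study()` orchestrate the factorial bias/RMSE/coverage
study: per cell (scenario × $n$ × $\gamma_1$ × censoring rate × truncation
quantile) the truth is computed once by quadrature, the censoring rate is
calibrated once, and each replication computes the naive, KM-IPCW and
Cox-IPCW estimators, optionally with Wald (KM) and percentile-bootstrap
intervals. Failed replications are excluded and counted; a cell aborts
above 5% failures. Summaries report bias ×100, RMSE ×100, the empirical
sd, the mean asymptotic/bootstrap SEs, coverage, and the Monte Carlo
standard error of the bias so that comparisons with published values can
be tolerance-principled.

The package's own acceptance checks run the four headline cells at 200
replications (bias table) and the SE/coverage cell at 500 replications —
sizes chosen so the whole suite completes comfortably on one core while
keeping Monte Carlo standard errors around 0.1–0.3 on the ×100 scale; the
full 1000-replication study is a single `run_study()` configuration away.
The bootstrap replicate count behind published coverage figures is not
stated in the source material; the runner defaults to 500 per interval
when enabled.

## Known limitations

* Pair sums are dense $O(n^2)$ by design (auditable against the formulas;
  C kernels keep $n = 10^5$ Monte Carlo truths in the tens of seconds);
  beyond a few times $10^4$ subjects the estimators become slow, and the
  dense-matrix helpers (`compute_pair_weights()`,
  `asymptotic_se_km()`) are meant for cohorts of a few thousand.
* No left truncation, interval censoring, time-dependent covariates, or
  more than two competing causes (merge further causes into code 2
  explicitly before analysis).
* The asymptotic variance covers independent censoring only; use the
  bootstrap under the Cox censoring model.
* Cross-validation for the no-independent-test-set situation is out of
  scope; predictions are consumed, never fitted.

## A worked example

```{r example, eval = FALSE}
library(crcindex)

scen <- sim_scenario("CR1", gamma1 = 0, lambda0_cens = 0.93)
t75 <- marginal_quantile(scen, 0.75)
cohort <- apply_censoring(simulate_uncensored(scen, 1000, seed = 1), scen, 1)

concordance_naive(cohort, cohort$covariates$x, t = t75)
concordance_ipcw(cohort, cohort$covariates$x, t = t75)
asymptotic_se_km(cohort, cohort$covariates$x, t = t75)
true_concordance(scen, t75)
```
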
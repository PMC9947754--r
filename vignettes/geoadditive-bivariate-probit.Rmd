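---
title: "A Bayesian geoadditive distributional bivariate probit: model, priors and sampler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian geoadditive distributional bivariate probit: model, priors and sampler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Stunting (height-for-age z-score strictly below −2 against the WHO growth
standard) and wasting (weight-for-height z-score strictly below −2) are the
standard markers of chronic and acute childhood undernutrition.  They are
measured on the same child at the same visit, so treating them as two
separate univariate regressions discards the information in their
dependence — and the dependence itself is of policy interest: where do the
two forms of malnutrition co-occur, and for which children?

`geobivprobit` fits both outcomes jointly.  For child $i$, outcomes
$(Y_{i1}, Y_{i2})$ arise by thresholding a latent bivariate normal pair,

$$
(Y^*_{i1}, Y^*_{i2})' \sim \mathrm{N}_2\!\left(
(\mu_{i1}, \mu_{i2})',\;
\Sigma_i = \begin{pmatrix} 1 & \rho_i \\ \rho_i & 1 \end{pmatrix}\right),
\qquad Y_{ij} = \mathbf{1}\{Y^*_{ij} > 0\},
$$

with unit latent variances for identifiability.  This is a *distributional*
regression: not only the two probit means but also the latent correlation
carry their own structured additive predictor,

$$
\mu_{i1} = \eta^{\mu_1}_i, \qquad
\mu_{i2} = \eta^{\mu_2}_i, \qquad
\rho_i = \tanh(\eta^{\rho}_i),
$$

the identity link for the means and the inverse Fisher z-transformation for
the correlation, which maps any real predictor into $(-1, 1)$.  Each
predictor is geoadditive:

$$
\eta^{\theta}_i = \beta^{\theta}_0 + u_i'\gamma^{\theta}
  + f^{\theta}_1(\text{child age}_i) + f^{\theta}_2(\text{mother age}_i)
  + f^{\theta}_{\mathrm{spat}}(s_i),
$$

with dummy-coded categorical covariates $u$, smooth functions of the
continuous covariates, and a discrete spatial effect over the region $s_i$
of residence.

## Priors

* **Linear effects** get flat (improper uniform) priors.
* **Smooth functions** are Bayesian P-splines: cubic B-splines on 20
  equidistant knots spanning the observed covariate range, giving
  $20 + 3 - 1 = 22$ basis functions (the knot count is read in the BayesX
  `nrknots` convention), with a second-order random-walk prior on adjacent
  coefficients, i.e. the partially improper Gaussian prior with precision
  $K/\tau^2$, $K = \Delta_2'\Delta_2$, $\operatorname{rank}(K) = 22 - 2$.
  Constants and linear trends in the coefficients are unpenalised.
* **Spatial effects** get the intrinsic Gaussian Markov random field
  (CAR) prior: conditional on the rest, the effect of region $s$ is normal
  with mean the average over its neighbours $N(s)$ and variance
  $\tau^2/|N(s)|$; equivalently, precision $K/\tau^2$ with
  $K = \operatorname{diag}(|N(s)|) - A$, rank $S$ minus the number of
  connected map components.
* **Smoothing variances** $\tau^2$ get independent inverse-gamma
  hyperpriors, IG$(a, b)$ with $a = b = 0.001$ by default — the
  conventional weakly informative choice of the structured additive
  regression literature; both are configurable in `sampler_config()`.

## Identifiability

The RW2 and GMRF priors are flat along the constant direction, which is
confounded with the intercept.  After each accepted update, spline blocks
are recentred so the fitted curve averages to zero over the observed
covariate values (B-spline rows form a partition of unity, so subtracting a
constant from all coefficients shifts the curve by exactly that constant),
and spatial blocks are recentred to an unweighted zero mean over regions; in
both cases the constant moves into the intercept, so every $\eta$ and the
penalty value are unchanged and the move is posterior-invariant.  An
unweighted (rather than observation-weighted) sum-to-zero convention was
chosen for the spatial term; for the splines, centring over the data makes
`summarize_curve()` directly comparable across parameters.  Regions with no
neighbours (islands) are kept at a fixed zero spatial effect and flagged —
with an island present, recentring of that block is skipped, since moving a
constant into the intercept would alter the island records' predictors.

## Posterior simulation

All blocks are updated by Metropolis-Hastings with IWLS Gaussian proposals
(Gamerman-style), sweeping all blocks of $\mu_1$, then $\mu_2$, then
$\rho$, then the variances.  For a block with design $Z$ and penalty $K$,
the proposal is

$$
\beta^\ast \sim \mathrm{N}\!\left(P^{-1} Z'W\tilde y,\; P^{-1}\right),
\qquad P = Z'WZ + K/\tau^2,
$$

where the working response $\tilde y = Z\beta + W^{-1}u$ is built from the
score $u_i = \partial \log p_i / \partial \eta_i$ and the *expected*
information $W_i = \sum_c (\partial p_{ic}/\partial \eta_i)^2 / p_{ic}$
(sum over the four outcome cells) of the exact bivariate probit
likelihood.  The acceptance ratio uses the exact likelihood and the full
proposal asymmetry: the reverse proposal is rebuilt at the proposed state.
Expected (rather than observed) information guarantees a positive
semidefinite proposal precision.  The smoothing variances are conjugate:
$\tau^2 \mid \beta \sim \mathrm{IG}(a + \operatorname{rank}(K)/2,\;
b + \beta'K\beta/2)$, drawn exactly.

The likelihood needs the bivariate normal CDF per record.  We implement
the Genz (2004) rewrite of the Drezner–Wesolowsky quadrature in C++
(absolute error around $10^{-14}$, far below the $10^{-8}$ accuracy the
acceptance ratio needs) and verify it in the tests against an independent
one-dimensional reduction computed with `integrate()` and against
closed-form orthant probabilities, e.g.
$P(Y_1{=}1, Y_2{=}1) = \tfrac14 + \arcsin(\rho)/2\pi$ at zero means.

Numerical safeguards: cell probabilities are floored at $10^{-300}$ before
logs (the log-likelihood is always finite), at $10^{-12}$ inside scores and
weights; weights are capped at $10^7$; the proposal precision carries a
$10^{-8}$ ridge (harmless for correctness — the same density is used for
drawing and in the ratio); $|\rho|$ is clamped to $1 - 10^{-10}$.  A
failed Cholesky factorisation rejects the update rather than aborting; a
non-finite log-likelihood after a sweep aborts with a diagnostic.

Defaults are 12 000 sweeps, 2 000 burn-in, thinning 10.  The calibration
and recovery studies in the test-suite use reduced chains — 4 000 sweeps,
1 000 burn-in, thinning 5 (600 kept draws) — which the IWLS proposals'
high acceptance rates make sufficient.  Chains are a pure function of
(data, spec, config, seed): the C++ core draws through R's RNG.

## The synthetic-data generator

Because the motivating survey microdata is access-restricted, every stage
is exercised on synthetic data with *known* effects, matched to the study's
scale: $n = 2000$ children by default on an 8×9 rook-adjacency lattice (72
regions, close to the 75 districts of the study), stunting/wasting-style
prevalences 40.7% / 9.7% via intercepts
$\Phi^{-1}(0.407), \Phi^{-1}(0.097)$.  Scenarios:

* `null` — everything zero (50% prevalences, independent outcomes); used
  for interval-calibration runs.
* `intercepts_only` — prevalence-matched intercepts only; the preset whose
  empirical prevalences emulate the study's descriptive rates.
* `linear_only` — prevalence-matched intercepts plus linear effects of
  three *binary* covariates (coefficients up to 0.35 in absolute value on
  the means, up to 0.15 on the Fisher-z correlation).  Binary covariates
  are deliberate: a recovery check that demands every posterior mean within
  0.15 of truth needs each design cell populated enough that 0.15 is
  several posterior standard deviations.  From the probit Fisher
  information at the wasting prevalence (~0.33 per observation at
  $\mu \approx -1.3$), a two-level covariate at $n = 4000$ gives
  coefficient posterior SDs near 0.055, so the tolerance sits at ~2.7 SDs;
  five-level factors would halve the per-level information and turn the
  all-coefficients check into a coin flip for a perfectly correct sampler.
* `full_geoadditive` — study-style categoricals (wealth quintile,
  toilet type, four-level food security), centred sinusoidal age effects
  (amplitudes 0.35/0.30 on the means, 0.20 on the correlation), and
  spatial fields drawn from a proper GMRF surrogate with precision
  $K + 10^{-6} I$ (the intrinsic prior itself is improper), centred to sum
  to zero and rescaled to fixed spreads (SD 0.30 / 0.25 / 0.15 for
  $\mu_1/\mu_2/\rho$) so the effect size is comparable across seeds.

Latent pairs are drawn per record by the Cholesky construction, since
$\rho_i$ varies with covariates.  Categorical levels, ages (uniform on
months 6–59 and years 15–49) and regions are drawn uniformly — the
generator emulates the *model's* assumed structure, not the joint covariate
distribution, survey weights or cluster design of a real DHS sample.
Passing recovery tests therefore demonstrates correctness of the inference
machinery under the model, not robustness to design features real data
would add.

## What the tests establish

* Orthant probabilities and the full likelihood against closed forms and
  independent quadrature (tolerances $10^{-8}$ and $10^{-6}$).
* Penalty algebra: explicit RW2 cross-product, null spaces, GMRF ranks and
  row sums.
* The conjugate $\tau^2$ step against inverse-gamma moments and an
  independent inverse-gamma sampler (Kolmogorov–Smirnov).
* Sampler validity on a flat-likelihood stub (proposal coincides with the
  prior conditional; acceptance 1) and against a one-dimensional
  profile-likelihood grid search.
* Calibration: across 20 null-scenario replicate studies
  ($n = 2000$, 72 regions, 4 000 sweeps each), the pooled share of 95%
  credible intervals of non-intercept linear coefficients covering zero
  must be at least 90%.
* Recovery at $n = 4000$: every linear coefficient on both means within
  0.15 of truth; true age curves inside the 95% band at ≥ 90% of grid
  points; spatial posterior means correlated with the true fields
  ($r > 0.6$) on both means; fitted per-record correlations
  $\hat\rho_i = \tanh(\overline{\eta^{\rho}_i})$ correlated with truth
  ($r > 0.6$).
* Screening: Pearson $\chi^2$ type-I rate within $[0.03, 0.07]$ at the 5%
  level over 2 000 independent tables; VIF of an $r = 0.7$ pair near the
  closed form $1/(1-0.49) \approx 1.96$.

The recovery criteria for curves and spatial fields are applied to the two
mean parameters.  The $\rho$ surface is intrinsically much harder at this
sample size — binary pairs carry little information about a
covariate-dependent correlation — and its spatial field is not expected to
reach the same correlation with truth; the per-record $\hat\rho_i$ check
covers the correlation predictor as a whole.

## Design choices where the field leaves room

* **"Twenty equidistant knots"** is read as the BayesX `nrknots`
  convention: 20 knots spanning the range, hence 19 interior intervals and
  22 cubic B-splines.
* **Strict threshold**: a z-score of exactly −2 is a non-case.
* **Union screening rule**: a categorical covariate enters the model when
  its $\chi^2$ p-value against *either* outcome is below $\alpha = 0.05$;
  continuous covariates bypass screening and always enter as smooths; no
  continuity correction.
* **VIF on the dummy-coded linear design** of the selected covariates
  only, one value per column, `Inf` flagging exact collinearity.
* **The correlation carries the same covariate set as the means**, so
  linear, nonlinear and spatial effects are reported for all three
  parameters.
* **Equal-tailed credible intervals** (not HPD); "significant" means the
  95% interval excludes zero; the spatial three-class map codes
  significantly positive / not significant / significantly negative.
* **Block structure**: one dummy-coded linear block (with intercept), one
  block per smooth, one spatial block — per parameter; update order
  groups blocks by parameter.

## Limitations

Exactly two outcomes, probit links, unit latent variances; no tensor or
varying-coefficient terms; no continuous (kriging) spatial effects; no
survey weights or multistage design corrections; single-chain diagnostics
(split-$\hat R$ and Geyer ESS) rather than multi-chain ones.  On maps with
islands the spatial level is weakly identified (centring is skipped).  Real
district shapefiles are out of scope — spatial output is tabular plus toy
lattice maps.
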
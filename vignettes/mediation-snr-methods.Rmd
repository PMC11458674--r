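---
title: "Signal-to-noise ratios for the mediation indirect effect: model, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal-to-noise ratios for the mediation indirect effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medsnr)
```

## The problem

Mediation analysis asks whether a predictor affects an outcome through an
intermediate variable. With latent constructs measured by error-prone
indicators, two families of methods compete. Structural equation modeling
(SEM) fits the full measurement-plus-structural model by normal-theory
maximum likelihood (NML) and estimates the latent indirect effect
$\gamma_1\beta_1$. Path analysis with weighted composites (PAWC) first
collapses each indicator block into a single score — a Bartlett-factor score
or an equally weighted composite — and then runs two ordinary regressions,
estimating a composite indirect effect $ab$.

The sizes of $\gamma_1\beta_1$ and $ab$ are not comparable: both depend on
the scales assigned to latent variables or composites, and those scales are
conventions (anchor loadings, unit factor variances, sum versus average
scores). What *is* comparable is the signal-to-noise ratio
$$\tau \;=\; \frac{\theta}{\mathrm{SD}(\sqrt{N}\,\hat\theta)},$$
which is free of the chosen scales and (asymptotically) of the sample size,
and which governs the power of any test of $H_0{:}\ \theta = 0$. `medsnr`
computes $\tau$ for the indirect effect — and for the three component path
coefficients — under four methods: SEM, Bartlett-factor scores with
population weights (`paBFS_w`), Bartlett-factor scores with estimated
weights (`paBFS_what`), and equally weighted composites (`paEWC`).

## The model

Three latent variables, each with its own indicator block:
$$x = \lambda_x \xi + e_x, \qquad
  y_1 = \lambda_{y_1}\eta_1 + e_{y_1}, \qquad
  y_2 = \lambda_{y_2}\eta_2 + e_{y_2},$$
$$\eta_1 = \gamma_1 \xi + \zeta_1, \qquad
  \eta_2 = \beta_1 \eta_1 + \gamma_2 \xi + \zeta_2.$$
Errors are mutually independent and independent of the factors; error
covariance matrices are diagonal. Identification fixes
$\mathrm{Var}(\xi) = 1$ and the first loading of each endogenous block at 1
(the *anchor* indicators). With three indicators per block this leaves
$q = 21$ free parameters ("base parameters"): nine loadings minus two
anchors, nine error variances, three structural coefficients, and two
structural residual variances. All parameters live in `base_params()`; the
implied covariance $\Sigma(\theta) = \Lambda\Phi\Lambda' + \Psi$ is built by
`implied_covariance()`.

Every SNR the package reports is invariant to re-identification: changing
the anchor values or fixing factor variances instead of loadings rescales
estimates and standard deviations together. The test suite asserts this to
`1e-8`.

## SNR under SEM

`nml_fit()` minimizes the ML discrepancy
$F_{ML}(\theta) = \mathrm{tr}(S\Sigma^{-1}) - \log|S\Sigma^{-1}| - p$
with an analytic gradient (a quasi-Newton method with the variance
parameters bounded below, which keeps $\Sigma(\theta)$ positive definite
throughout and turns would-be negative variance estimates into flagged
boundary solutions — "Heywood" cases). `expected_information()` evaluates
the per-observation expected information
$I_{jk} = \tfrac{1}{2}\mathrm{tr}(\Sigma^{-1}\dot\Sigma_j\Sigma^{-1}\dot\Sigma_k)$
from analytic derivatives $\dot\Sigma_j$; a finite-difference Hessian is
kept as a test oracle only. With $V = I(\theta)^{-1}$ and
$(v_{gg}, v_{bb}, v_{gb})$ the block of $(\hat\gamma_1, \hat\beta_1)$, the
delta method gives
$$\omega_{\gamma_1\beta_1} = \big(\beta_1^2 v_{gg} + \gamma_1^2 v_{bb}
   + 2\beta_1\gamma_1 v_{gb}\big)^{1/2}, \qquad
  \tau_{\gamma_1\beta_1} = \gamma_1\beta_1/\omega_{\gamma_1\beta_1}.$$
Because the information is per observation, $\sqrt{N}$ never enters.

## SNR under PAWC conditional on weights

A composite $w'x$, normalized so $w'\lambda = 1$, equals the factor plus an
uncorrelated error ("1-1 link"), with reliability
$\rho = (w'\lambda)^2\sigma_f^2 / \{(w'\lambda)^2\sigma_f^2 + w'\Psi w\}$
and variance $\sigma^2_f/\rho$. Bartlett weights $w \propto \Psi^{-1}\lambda$
maximize $\rho$; equal weights ignore the item properties. Since the
composite covariances equal the latent covariances, the population
regression coefficients follow from the normal equations on composite
moments: $a = \rho_{\hat\xi}\gamma_1$, and $(b, c)$ solve the 2×2 system
with predictors $(\hat\eta_1, \hat\xi)$. The asymptotic variances of the LS
estimates follow from the standard formulas with population moments, and,
because $\hat a \perp \hat b$ under joint normality,
$$\omega^2_{abw} = a^2\omega^2_{bw} + b^2\omega^2_{aw}, \qquad
  \tau_{abw} = \frac{ab}{\omega_{abw}}
  = \Big(\tau_{aw}^{-2} + \tau_{bw}^{-2}\Big)^{-1/2}.$$
The harmonic-mean identity is asserted to `1e-10` on every generated
condition. The residual variance of the second regression is assembled from
the same moment algebra rather than transcribed from a printed closed form;
a large-sample simulation oracle confirms the equality.

## SNR under PAWC with estimated weights

In practice Bartlett weights are computed from NML estimates of a
confirmatory factor model fitted to the same sample, so the weights carry
sampling error. The estimate $\hat a\hat b$ is then a smooth function
$g(S)$ of the sample covariance matrix:
$$S \;\to\; \hat\theta(S) \;\to\; \hat w(\hat\theta) \;\to\;
  \text{composite moments } W'SW \;\to\; (\hat a, \hat b, \hat c)
  \;\to\; \hat a \hat b,$$
and the delta method over $\mathrm{vech}(S)$ gives
$\omega^2_{ab\hat w} = \nabla g' \,\Gamma\, \nabla g$, where
$\Gamma_{(ij),(kl)} = \sigma_{ik}\sigma_{jl} + \sigma_{il}\sigma_{jk}$ is
the normal-theory asymptotic covariance of $\sqrt{N}\,\mathrm{vech}(S)$.

Two design choices matter here.

**The estimator map is linearized analytically.** Instead of refitting the
model at perturbed covariance matrices, the package uses the exact
first-order expansion of the NML estimator,
$\partial\hat\theta/\partial\mathrm{vech}(S) = (\Delta'W\Delta)^{-1}\Delta'W$
with $\Delta = \partial\,\mathrm{vech}(\Sigma)/\partial\theta'$ and $W$ the
normal-theory weight matrix ($\Delta'W\Delta$ is the expected information).
This is mathematically identical to differentiating the inner-fit map at
the population point, avoids finite-difference noise from an iterative
optimizer, and is two orders of magnitude faster. A test compares it
against a literal refit-and-difference route, and a Monte Carlo study with
per-replication re-estimated weights confirms $\omega_{ab\hat w}$ to within
Monte Carlo error. The remaining outer derivatives (coefficients with
respect to moments and weights) use central differences with step
$10^{-5}$ times the scale of the perturbed quantity; results are stable to
`1e-3` relative under step halving.

**Estimated weights are those of the variance-standardized factor
solution.** Factor scores in practice come from a CFA whose factors are
standardized to unit variance, so each block's Bartlett weights are divided
by the *fitted* factor SD. That standardization is data-dependent and is
part of the estimator: its sampling variation is negatively coupled with
the LS coefficients' variation, which is why estimated weights usually
*reduce* the SD of $\hat a\hat b$ — the same phenomenon known from other
settings where plugging in efficiently estimated nuisance parameters
shrinks the asymptotic variance of a downstream statistic. Had the weights
been normalized against the anchor-identified solution instead, the weight
channel would only add noise and estimated weights would always look worse
than fixed ones; numerically, only the standardized formulation reproduces
the documented dominance of `paBFS_what` over `paBFS_w` (about 87% of
random conditions). For comparability, the package reports the resulting
coefficients back on the 1-1 link scale through a fixed population
rescaling, which leaves every SNR untouched and makes
$\omega_{ab\hat w}$ reduce exactly to $\omega_{abw}$ when the weight
channel is switched off (`weight_sensitivity = FALSE`).

## The condition generator

`generate_conditions()` draws each of the 21 free parameters independently
from Uniform(0.2, 1.2) — a unit-interval draw shifted by 0.2 so that no
loading, variance, or structural coefficient sits near zero, where SNRs
degenerate and ML fits become fragile. These are the *study conditions*:
loadings and error variances of realistic, heterogeneous size, reliabilities
mostly between 0.3 and 0.9, and structural effects spanning weak to strong.
The generator emulates the covariance structure of normally distributed
indicator data exactly; it does **not** emulate nonnormality (heavy tails,
skewness), missing data, categorical items, cross-loadings, or correlated
errors. Conclusions drawn from passing tests therefore speak to the
normal-theory, correctly specified case — the setting that most favors SEM,
which makes the composite methods' advantage conservative rather than
flattering.

The mapping of the 21 draws onto parameters follows the fixed documented
order of `as_theta()`; since the draws are i.i.d., any fixed order is
distributionally equivalent. All randomness is seeded: condition sets carry
their seed, and the Monte Carlo engine derives one RNG stream per condition
from the master seed so results do not depend on execution order.

## The Monte Carlo engine and its scale

`population_batch()` evaluates the four population SNRs per condition with
no simulation. `empirical_snr()` simulates: per condition and replication
it draws $N$ observations from $N(0, \Sigma(\theta))$, fits the SEM by NML
(started at the true parameters, as is standard in simulation studies),
recomputes Bartlett weights from the fitted solution, scores the data, and
runs the two LS regressions; the empirical SNR is
$\hat\tau = \bar\theta / (\sqrt{N}\,\mathrm{SD}(\hat\theta))$ over
replications.

Non-convergence policy: a replication whose fit fails to converge or hits a
variance boundary is retried once from a perturbed start, then excluded and
counted; a condition is dropped when more than 10% of its replications
fail. Exclusion logs travel with every batch, because at $N = 200$ boundary
solutions are not rare under wide random conditions (typically a few
percent of replications, concentrated in low-reliability conditions).

Default problem sizes are chosen for a desk-scale reproduction: the
population comparison uses 1000 conditions (seconds to minutes), and the
empirical comparison uses 50 conditions × 400 replications at $N = 200$.
The 400 replications are a precision choice: the replication noise in
$\hat\tau$ enters the empirical-versus-population $R^2$ as roughly
$1/n_{\mathrm{reps}}$, and 400 keeps that contribution near 1% so the
$R^2$ reflects the asymptotic agreement rather than Monte Carlo error. A
full-scale study (1000 × 1000) uses the same code path and only changes
these arguments.

## Numerical choices

* Positive definiteness of $\Sigma$ is guaranteed during optimization by
  bounding variance parameters below (`1e-6`); validation elsewhere uses a
  smallest-eigenvalue threshold of `1e-10`.
* Default starting values when the truth is unknown: unit loadings, error
  variances at half the observed variances, and structural starts from an
  equally-weighted-composite path analysis of the input matrix.
* The likelihood-ratio statistic is $(N-1)\,F_{ML}$ with the divisor-$N$
  sample covariance, the convention used by covariance-matrix-input SEM
  software.
* LS path regressions include intercepts; population results refer to
  mean-centered variables, so the intercepts are asymptotically irrelevant.
* Degenerate inputs fail loudly: collinear score matrices, non-PD input
  covariances, zero composite signal ($w'\lambda = 0$), and single-
  replication empirical designs all raise informative errors.

## Known limitations

* Normal-theory only: with heavy-tailed data the SEM standard errors
  degrade faster than composite-based ones, so the comparisons here are, if
  anything, favorable to SEM.
* No model misspecification: cross-loadings or error covariances are
  deliberately out of scope, as path analysis has no matching way to
  represent them.
* The SNR describes efficiency/power, not type-I error control, which
  in applied mediation analysis is handled by bootstrap or Monte Carlo
  intervals regardless of the method.
* Best-subset regression on the covariate table is left to standard tools;
  `covariates_and_correlations()` exports the 37 candidate predictors of
  the SNR difference with their marginal correlations.
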
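# medsnr

Signal-to-noise ratios (SNR) for estimating and testing the **indirect
effect** in mediation analysis: structural equation modeling (SEM) versus
path analysis with weighted composites (PAWC).

## The problem

In a three-construct mediation model, a predictor ξ affects an outcome η₂
through a mediator η₁, each construct measured by its own block of
error-prone indicators:

    x  = λₓ ξ + eₓ,   y₁ = λ_y₁ η₁ + e_y₁,   y₂ = λ_y₂ η₂ + e_y₂
    η₁ = γ₁ ξ + ζ₁,   η₂ = β₁ η₁ + γ₂ ξ + ζ₂

The indirect effect is γ₁β₁ under SEM, or *ab* when the two regressions are
run on weighted composite scores (Bartlett-factor scores or equally
weighted composites). Because latent variables and composites have no
intrinsic units, the *sizes* of γ₁β₁ and *ab* are artifacts of scaling
conventions and cannot be compared. What can be compared is each
estimator's **signal-to-noise ratio**

    τ = θ / SD(√N · θ̂),

a scale-free, sample-size-free quantity that directly governs the power of
any test of a zero indirect effect. `medsnr` computes τ for four methods —
SEM (`SEM`), path analysis with Bartlett-factor scores using population
weights (`paBFS_w`) or estimated weights (`paBFS_what`), and equally
weighted composites (`paEWC`) — both analytically (population SNRs, via the
expected information, the delta method, and closed-form composite moment
algebra) and empirically (seeded Monte Carlo). It is aimed at methodologists
studying the efficiency of mediation analyses and at applied researchers
deciding between SEM and factor-score regression for a given measurement
design.

Core machinery: normal-theory ML estimation of the mediation SEM with
analytic gradients and expected-information standard errors; Bartlett and
equal-weight composites with reliabilities; closed-form population path
coefficients and asymptotic variances conditional on weights; a delta
method over the sample covariance matrix that accounts for sampling error
in estimated factor-score weights; and a condition generator plus Monte
Carlo engine for batch comparisons.

## Worked example

```r
library(medsnr)

bp <- base_params(
  lambda_x  = c(0.8, 0.7, 0.9),
  lambda_y1 = c(1, 0.6, 0.7), lambda_y2 = c(1, 0.8, 0.5),
  psi_x  = c(0.5, 0.4, 0.3), psi_y1 = c(0.4, 0.5, 0.6),
  psi_y2 = c(0.3, 0.4, 0.5),
  gamma1 = 0.5, gamma2 = 0.3, beta1 = 0.4,
  sigma2_zeta1 = 0.6, sigma2_zeta2 = 0.7)

population_snr_sem(bp)
#> Population SNR under SEM
#>   tau(gamma1) = 0.4497  tau(gamma2) = 0.2160  tau(beta1) = 0.2462
#>   tau(gamma1*beta1) = 0.2267  (omega = 0.8821)

spec <- bartlett_weights(bp)
pawc_population(bp, spec)
#> PAWC population quantities [bartlett weights]
#>   a = 0.4194  b = 0.3156  c = 0.2870  ab = 0.1324
#>   tau_a = 0.4860  tau_b = 0.3081  tau_c = 0.2920  tau_ab = 0.2602

snr_estimated_weights(bp)
#> PAWC SNR with estimated Bartlett weights
#>   tau_ab = 0.2705  (omega_ab = 0.4894)
#>   tau: a 0.5350  c 0.2993  b 0.3143  ab 0.2705
```

Reading the output: under SEM the indirect-effect SNR is 0.227. Replacing
the latent variables by Bartlett-factor scores changes the estimand
(*ab* = 0.132 ≠ γ₁β₁ = 0.20 — the attenuated composite effect) but
*increases* the SNR to 0.260; accounting for the sampling error in the
estimated weights raises it further to 0.271. For this measurement design,
factor-score path analysis detects the mediation effect with more power
than full SEM, and estimating the weights helps rather than hurts.

Batch comparison over randomly generated parameter conditions:

```r
conds <- generate_conditions(200, seed = 20260925)
batch <- population_batch(conds)
s <- summary(batch); s[s$parameter == "ab", ]
#>        method parameter    min   max median  mean    sd    cv
#> 4         SEM        ab 0.0554 0.518  0.253 0.260 0.106 0.407
#> 8     paBFS_w        ab 0.0899 0.662  0.364 0.371 0.131 0.353
#> 12 paBFS_what        ab 0.0902 0.792  0.380 0.394 0.152 0.386
#> 16      paEWC        ab 0.0970 0.623  0.346 0.350 0.124 0.355

pc <- pairwise_counts(batch); pc[pc$smaller == "SEM", c("greater", "ab", "n")]
#>       greater  ab   n
#> 4     paBFS_w 179 200
#> 7  paBFS_what 189 200
#> 10      paEWC 151 200
```

SEM yields the smallest indirect-effect SNR on average, and is beaten by
Bartlett-factor-score path analysis in about nine of ten random conditions.
`empirical_snr()` runs the matching finite-sample simulation
(`N`, replications, and seed all explicit), and
`covariates_and_correlations()` exports the 37 candidate predictors of the
per-condition SNR difference.

A thin command-line interface over the same functions lives at
`inst/cli/medsnr.R` (subcommands `conditions`, `snr-pop`, `simulate`,
`fit`); covariance-matrix input files for `fit` are described in
`?read_covariance_input`, with a synthetic example under `inst/extdata/`.

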
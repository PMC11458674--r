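test_that("expected information matches the numeric curvature of the discrepancy", {
  bp <- fixture_params()
  mom <- implied_covariance(bp)
  f <- function(th) {
    s <- medsnr:::sigma_sem(th)$sigma
    sum(mom$sigma * chol2inv(chol(s))) +
      as.numeric(determinant(s)$modulus - determinant(mom$sigma)$modulus) - 9
  }
  H <- pracma::hessian(f, unname(as_theta(bp)))
  I <- expected_information(bp)
  expect_rel_equal(H / 2, I, 1e-5)
  expect_true(isSymmetric(unname(I), tol = 1e-10))
  expect_gt(min(eigen(I, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("permuting indicators within a block permutes the SNR-irrelevant structure", {
  bp <- fixture_params()
  perm <- base_params(bp$lambda_x[c(2, 1, 3)], bp$lambda_y1, bp$lambda_y2,
                      bp$psi_x[c(2, 1, 3)], bp$psi_y1, bp$psi_y2,
                      bp$gamma1, bp$gamma2, bp$beta1,
                      bp$sigma2_zeta1, bp$sigma2_zeta2)
  s1 <- population_snr_sem(bp)
  s2 <- population_snr_sem(perm)
  expect_equal(s2$tau_indirect, s1$tau_indirect, tolerance = 1e-10)
  expect_equal(s2$tau_gamma1, s1$tau_gamma1, tolerance = 1e-10)
})

test_that("SNRs are invariant to re-identification of the latent scales", {
  bp <- fixture_params()
  s0 <- population_snr_sem(bp)
  for (args in list(list(k1 = 2), list(k2 = 0.5), list(c2 = 4),
                    list(k1 = 1.7, k2 = 0.6, c2 = 2.25))) {
    bp2 <- do.call(reidentify_params, c(list(bp), args))
    s2 <- population_snr_sem(bp2)
    expect_equal(s2$tau_gamma1, s0$tau_gamma1, tolerance = 1e-8)
    expect_equal(s2$tau_gamma2, s0$tau_gamma2, tolerance = 1e-8)
    expect_equal(s2$tau_beta1, s0$tau_beta1, tolerance = 1e-8)
    expect_equal(s2$tau_indirect, s0$tau_indirect, tolerance = 1e-8)
  }
})

test_that("tau_indirect equals gamma1*beta1 / omega exactly", {
  s <- population_snr_sem(fixture_params())
  bp <- fixture_params()
  expect_identical(s$tau_indirect, bp$gamma1 * bp$beta1 / s$omega_indirect)
})

test_that("fitting the exact implied covariance recovers the parameters", {
  bp <- fixture_params()
  sigma <- implied_covariance(bp)$sigma
  fit <- nml_fit(sigma, N = 500, start = NULL)   # default start, not truth
  expect_true(fit$converged)
  expect_false(fit$heywood)
  expect_lt(fit$fmin, 1e-9)
  expect_lt(abs(fit$test_stat), 1e-6)
  expect_equal(fit$df, 24L)
  expect_equal(unname(fit$theta_hat), unname(as_theta(bp)), tolerance = 1e-4)
  expect_true(isSymmetric(unname(fit$vcov), tol = 1e-8))
})

test_that("CFA variant fits the implied covariance with df 24", {
  bp <- fixture_params()
  sigma <- implied_covariance(bp)$sigma
  fit <- nml_fit(sigma, N = 500, model = "cfa")
  expect_true(fit$converged)
  expect_lt(fit$fmin, 1e-8)
  expect_equal(fit$df, 24L)
  # fitted factor correlations equal the scaled latent covariances
  phi <- stats::cov2cor(latent_cov(bp))
  expect_equal(unname(fit$theta_hat[c("phi21", "phi31", "phi32")]),
               phi[lower.tri(phi)], tolerance = 1e-4)
})

test_that("estimates fall within 4 SE of the truth in simulated samples", {
  bp <- fixture_params()
  sigma <- implied_covariance(bp)$sigma
  R <- chol(sigma)
  N <- 200
  set.seed(2718)
  n_rep <- 100
  covered <- logical(n_rep)
  ok <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    X <- matrix(rnorm(N * 9), N, 9) %*% R
    S <- crossprod(sweep(X, 2, colMeans(X))) / N
    fit <- nml_fit(S, N, start = bp)
    ok[r] <- fit$converged && !fit$heywood && !is.null(fit$vcov)
    if (!ok[r]) next
    se <- sqrt(diag(fit$vcov) / N)
    covered[r] <- all(abs(fit$theta_hat - as_theta(bp)) < 4 * se)
  }
  expect_gt(mean(ok), 0.9)
  expect_gt(mean(covered[ok]), 0.95)
})

test_that("delta-method SE of the indirect effect reduces correctly", {
  bp <- fixture_params()
  sigma <- implied_covariance(bp)$sigma
  fit <- nml_fit(sigma, N = 400, start = bp)
  d <- indirect_se_delta(fit)
  idx <- medsnr:::sem_indices()
  g1 <- fit$theta_hat[idx$gamma1]; b1 <- fit$theta_hat[idx$beta1]
  expect_equal(d$estimate, unname(g1 * b1), tolerance = 1e-8)
  expect_equal(d$z, d$estimate / d$se)
  # gamma1 = 0: estimate 0 and SE = |beta1| sqrt(v_gg / N)
  fit0 <- fit
  fit0$theta_hat[idx$gamma1] <- 0
  d0 <- indirect_se_delta(fit0)
  expect_equal(d0$estimate, 0)
  expect_equal(d0$se,
               abs(unname(fit0$theta_hat[idx$beta1])) *
                 sqrt(fit0$vcov[idx$gamma1, idx$gamma1] / fit0$N))
  # symmetric in v_gg <-> v_bb when v_gb = 0 and gamma1 = beta1
  fit1 <- fit
  fit1$theta_hat[idx$gamma1] <- fit1$theta_hat[idx$beta1] <- 0.5
  fit1$vcov[idx$gamma1, idx$beta1] <- fit1$vcov[idx$beta1, idx$gamma1] <- 0
  d1 <- indirect_se_delta(fit1)
  fit2 <- fit1
  vgg <- fit1$vcov[idx$gamma1, idx$gamma1]
  fit2$vcov[idx$gamma1, idx$gamma1] <- fit1$vcov[idx$beta1, idx$beta1]
  fit2$vcov[idx$beta1, idx$beta1] <- vgg
  expect_equal(indirect_se_delta(fit2)$se, d1$se, tolerance = 1e-12)
})

test_that("nml_fit validates its input matrix", {
  bp <- fixture_params()
  sigma <- implied_covariance(bp)$sigma
  expect_error(nml_fit(sigma[1:8, 1:8], N = 100), "9 x 9")
  bad <- sigma; bad[1, 2] <- bad[1, 2] + 1
  expect_error(nml_fit(bad, N = 100), "symmetric")
  expect_error(nml_fit(sigma, N = 21), "exceed")
  expect_error(nml_fit(-sigma, N = 100), "positive definite")
})
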
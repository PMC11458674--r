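test_that("error-free composites recover the structural coefficients", {
  bp <- fixture_params()
  spec <- composite_spec(rep(1, 3), rep(1, 3), rep(1, 3), rho = c(1, 1, 1))
  pw <- pawc_population(bp, spec)
  expect_equal(pw$a, bp$gamma1, tolerance = 1e-12)
  expect_equal(pw$b, bp$beta1, tolerance = 1e-12)
  expect_equal(pw$c, bp$gamma2, tolerance = 1e-12)
  expect_equal(pw$ab, bp$gamma1 * bp$beta1, tolerance = 1e-12)
})

test_that("a and ab vanish when gamma1 is zero", {
  bp <- fixture_params()
  bp$gamma1 <- 0
  for (spec in list(bartlett_weights(bp), equal_weights(bp))) {
    pw <- pawc_population(bp, spec)
    expect_equal(pw$a, 0)
    expect_equal(pw$ab, 0)
  }
})

test_that("moment algebra equals the printed closed forms", {
  bp <- fixture_params()
  spec <- bartlett_weights(bp)
  pw <- pawc_population(bp, spec)
  mom <- implied_covariance(bp)
  rx <- spec$rho_xi; r1 <- spec$rho_eta1
  g1 <- bp$gamma1; g2 <- bp$gamma2; b1 <- bp$beta1
  s2e1 <- mom$sigma2_eta1; sz1 <- bp$sigma2_zeta1
  # a = rho_xi * gamma1
  expect_equal(pw$a, rx * g1, tolerance = 1e-12)
  # indirect effect closed form
  ab <- rx * r1 * g1 * (g1 * (b1 * g1 + g2) * (1 - rx) + b1 * sz1) /
    (sz1 + g1^2 * (1 - rx * r1))
  expect_equal(pw$ab, ab, tolerance = 1e-12)
  # b, c closed forms (shared denominator)
  den <- sz1 / (rx * r1) + g1^2 * (1 / (rx * r1) - 1)
  expect_equal(pw$b, (g1 * (b1 * g1 + g2) * (1 / rx - 1) + b1 * sz1 / rx) / den,
               tolerance = 1e-12)
  expect_equal(pw$c, (g1 * (b1 * s2e1 + g1 * g2) * (1 / r1 - 1) + g2 * sz1 / r1) / den,
               tolerance = 1e-12)
  # asymptotic variance closed forms
  expect_equal(pw$omega2_aw, rx * s2e1 / r1 - rx^2 * g1^2, tolerance = 1e-12)
  expect_equal(pw$omega2_bw, pw$sigma2_e2 / (s2e1 / r1 - rx * g1^2),
               tolerance = 1e-12)
  expect_equal(pw$omega2_cw, pw$sigma2_e2 * s2e1 / (s2e1 / rx - r1 * g1^2),
               tolerance = 1e-12)
  expect_equal(pw$omega_abw, sqrt(pw$a^2 * pw$omega2_bw + pw$b^2 * pw$omega2_aw))
})

test_that("the harmonic SNR identity holds for generated conditions", {
  conds <- generate_conditions(150, seed = 515)
  for (bp in conds) {
    for (spec in list(bartlett_weights(bp), equal_weights(bp))) {
      pw <- pawc_population(bp, spec)
      expect_equal(pw$tau_ab, (1 / pw$tau_a^2 + 1 / pw$tau_b^2)^(-1 / 2),
                   tolerance = 1e-10)
      expect_gt(pw$sigma2_e2, 0)
    }
  }
})

test_that("the composite indirect effect can exceed the latent one", {
  conds <- generate_conditions(300, seed = 616)
  exceeds <- vapply(conds, function(bp) {
    pw <- pawc_population(bp, bartlett_weights(bp))
    pw$ab > bp$gamma1 * bp$beta1
  }, logical(1))
  expect_gt(sum(exceeds), 0)
  expect_lt(sum(exceeds), length(conds))
})

test_that("population coefficients and omegas match a simulation oracle", {
  bp <- fixture_params()
  spec <- bartlett_weights(bp)
  pw <- pawc_population(bp, spec)
  # consistency: LS on a very large sample converges to (a, b, c)
  set.seed(4242)
  X <- simulate_indicators(bp, 4e5)
  f <- ls_fit_paths(score_composites(X, spec))
  expect_equal(f$a, pw$a, tolerance = 4 * f$se_a / abs(pw$a) + 1e-3)
  expect_equal(f$b, pw$b, tolerance = 4 * f$se_b / abs(pw$b) + 1e-3)
  expect_equal(f$c, pw$c, tolerance = 4 * f$se_c / abs(pw$c) + 1e-2)
  # omega_abw and independence of (a-hat, b-hat): replication study at N = 200
  N <- 200; reps <- 1500
  sigR <- chol(implied_covariance(bp)$sigma)
  W <- medsnr:::weight_matrix(spec)
  est <- matrix(NA_real_, reps, 2)
  for (r in seq_len(reps)) {
    X <- matrix(rnorm(N * 9), N, 9) %*% sigR
    ff <- ls_fit_paths(X %*% W)
    est[r, ] <- c(ff$a, ff$b)
  }
  sd_ab <- sqrt(N) * sd(est[, 1] * est[, 2])
  expect_lt(abs(sd_ab - pw$omega_abw) / pw$omega_abw, 0.08)
  # mean(a-hat) unbiased within 3 MC SEs; corr(a-hat, b-hat) near zero
  expect_lt(abs(mean(est[, 1]) - pw$a), 3 * sd(est[, 1]) / sqrt(reps))
  expect_lt(abs(cor(est[, 1], est[, 2])), 3 / sqrt(reps))
})

test_that("least-squares path fit agrees with lm and handles degeneracies", {
  bp <- fixture_params()
  set.seed(33)
  sc <- score_composites(simulate_indicators(bp, 150), bartlett_weights(bp))
  f <- ls_fit_paths(sc)
  m1 <- lm(sc[, 2] ~ sc[, 1])
  m2 <- lm(sc[, 3] ~ sc[, 2] + sc[, 1])
  expect_equal(f$a, unname(coef(m1)[2]), tolerance = 1e-10)
  expect_equal(f$se_a, summary(m1)$coefficients[2, 2], tolerance = 1e-10)
  expect_equal(f$b, unname(coef(m2)[2]), tolerance = 1e-10)
  expect_equal(f$c, unname(coef(m2)[3]), tolerance = 1e-10)
  expect_equal(f$se_b, summary(m2)$coefficients[2, 2], tolerance = 1e-10)
  expect_equal(f$sobel_se, sqrt(f$a^2 * f$se_b^2 + f$b^2 * f$se_a^2))
  # exact linear relation: slope recovered with zero residual error
  xi <- rnorm(50)
  sc0 <- cbind(xi, 0.5 * xi, rnorm(50))
  expect_error(ls_fit_paths(sc0), "collinear")
  sc1 <- cbind(xi, 0.5 * xi + rnorm(50, sd = 1e-6), rnorm(50))
  f1 <- ls_fit_paths(sc1)
  expect_equal(f1$a, 0.5, tolerance = 1e-5)
  expect_lt(f1$se_a, 1e-6)
  expect_error(ls_fit_paths(sc[1:3, ]), "at least 4")
})
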
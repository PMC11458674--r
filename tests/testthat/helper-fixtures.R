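# Shared fixtures: a fixed, hand-written condition with unequal loadings and
# error variances (so no accidental symmetry hides indexing mistakes), and a
# few helpers used across test files.

fixture_params <- function() {
  base_params(
    lambda_x = c(0.9, 0.7, 1.1),
    lambda_y1 = c(1.0, 0.8, 0.6),
    lambda_y2 = c(1.0, 0.5, 0.9),
    psi_x = c(0.5, 0.8, 0.4),
    psi_y1 = c(0.6, 0.9, 0.7),
    psi_y2 = c(0.4, 0.6, 0.8),
    gamma1 = 0.6, gamma2 = 0.4, beta1 = 0.5,
    sigma2_zeta1 = 0.7, sigma2_zeta2 = 0.9)
}

# re-identified copy: anchor of eta1 set to k1, of eta2 to k2, Var(xi) to c2;
# parameter changes leave Sigma(theta) untouched
reidentify_params <- function(bp, k1 = 1, k2 = 1, c2 = 1) {
  s <- sqrt(c2)
  base_params(
    lambda_x = bp$lambda_x / s,
    lambda_y1 = bp$lambda_y1 * k1,
    lambda_y2 = bp$lambda_y2 * k2,
    psi_x = bp$psi_x, psi_y1 = bp$psi_y1, psi_y2 = bp$psi_y2,
    gamma1 = bp$gamma1 / (k1 * s),
    gamma2 = bp$gamma2 / (k2 * s),
    beta1 = bp$beta1 * k1 / k2,
    sigma2_zeta1 = bp$sigma2_zeta1 / k1^2,
    sigma2_zeta2 = bp$sigma2_zeta2 / k2^2,
    sigma2_xi = c2)
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y)) / max(abs(y)), tol)
}
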
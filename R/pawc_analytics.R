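# Closed-form population quantities for path analysis with weighted
# composites (PAWC), conditional on the weights.

# second-order moments of the composites implied by (theta, reliabilities)
composite_moments <- function(bp, spec) {
  mom <- implied_covariance(bp)
  s2xi <- bp$sigma2_xi
  list(
    s2xi = s2xi,
    s2eta1 = mom$sigma2_eta1,
    s2eta2 = mom$sigma2_eta2,
    # composite variances, sigma^2_f / rho
    v_xi = s2xi / spec$rho_xi,
    v_eta1 = mom$sigma2_eta1 / spec$rho_eta1,
    v_eta2 = mom$sigma2_eta2 / spec$rho_eta2,
    # composite covariances equal the latent covariances (errors independent)
    c_xi_eta1 = bp$gamma1 * s2xi,
    c_xi_eta2 = (bp$beta1 * bp$gamma1 + bp$gamma2) * s2xi,
    c_eta1_eta2 = bp$beta1 * mom$sigma2_eta1 + bp$gamma1 * bp$gamma2 * s2xi)
}

#' Population path coefficients and SNRs under PAWC, conditional on weights
#'
#' Given the base parameters and a composite weighting scheme, computes the
#' population least-squares coefficients of the two path-analysis
#' regressions
#' \deqn{\hat\eta_1 = a \hat\xi + e_1, \qquad
#'       \hat\eta_2 = b \hat\eta_1 + c \hat\xi + e_2,}
#' the indirect effect \eqn{ab}, the asymptotic variances
#' \eqn{\omega^2_{aw}, \omega^2_{bw}, \omega^2_{cw}} of
#' \eqn{\sqrt{N}(\hat a, \hat b, \hat c)}, the delta-method SD
#' \eqn{\omega_{abw} = (a^2\omega^2_{bw} + b^2\omega^2_{aw})^{1/2}}
#' (valid because \eqn{\hat a \perp \hat b} under joint normality), and the
#' SNRs \eqn{\tau_{aw}, \tau_{bw}, \tau_{cw}} and
#' \eqn{\tau_{abw} = ab/\omega_{abw} =
#' (1/\tau_{aw}^2 + 1/\tau_{bw}^2)^{-1/2}}.
#'
#' All quantities are assembled from the composite moments: the composite
#' variances are \eqn{\sigma^2_f/\rho} for each block and the composite
#' covariances equal the latent covariances because measurement errors are
#' independent of the factors. In particular \eqn{a = \rho_{\hat\xi}\gamma_1}
#' and \eqn{a = \gamma_1, b = \beta_1, c = \gamma_2} when the composites are
#' error-free (\eqn{\rho = 1}).
#'
#' @param bp a [base_params()] object.
#' @param spec a `"composite_spec"` (only the reliabilities enter).
#' @return list of class `"pawc_population"` with fields `a`, `b`, `c`,
#'   `ab`, `sigma2_e1`, `sigma2_e2`, `omega2_aw`, `omega2_bw`, `omega2_cw`,
#'   `omega_abw`, `tau_a`, `tau_b`, `tau_c`, `tau_ab`.
#' @export
pawc_population <- function(bp, spec) {
  stopifnot(inherits(bp, "base_params"), inherits(spec, "composite_spec"))
  if (any(c(spec$rho_xi, spec$rho_eta1, spec$rho_eta2) <= 0))
    stop("composite reliabilities must be positive")
  m <- composite_moments(bp, spec)

  a <- m$c_xi_eta1 / m$v_xi                     # = rho_xi * gamma1
  # normal equations for (b, c) with predictors (eta1_hat, xi_hat)
  S11 <- matrix(c(m$v_eta1, m$c_xi_eta1, m$c_xi_eta1, m$v_xi), 2, 2)
  s12 <- c(m$c_eta1_eta2, m$c_xi_eta2)
  bc <- solve(S11, s12)
  b <- bc[1]; cc <- bc[2]
  ab <- a * b

  sigma2_e1 <- m$v_eta1 - a^2 * m$v_xi
  sigma2_e2 <- m$v_eta2 - b^2 * m$v_eta1 - cc^2 * m$v_xi -
    2 * b * cc * m$c_xi_eta1
  if (sigma2_e2 <= 0)
    stop("non-positive prediction-error variance sigma2_e2")

  S11inv <- solve(S11)
  omega2_aw <- sigma2_e1 / m$v_xi
  omega2_bw <- sigma2_e2 * S11inv[1, 1]
  omega2_cw <- sigma2_e2 * S11inv[2, 2]
  omega_abw <- sqrt(a^2 * omega2_bw + b^2 * omega2_aw)

  structure(list(
    a = a, b = b, c = cc, ab = ab,
    sigma2_e1 = sigma2_e1, sigma2_e2 = sigma2_e2,
    omega2_aw = omega2_aw, omega2_bw = omega2_bw, omega2_cw = omega2_cw,
    omega_abw = omega_abw,
    tau_a = a / sqrt(omega2_aw),
    tau_b = b / sqrt(omega2_bw),
    tau_c = cc / sqrt(omega2_cw),
    tau_ab = ab / omega_abw,
    scheme = spec$scheme),
    class = "pawc_population")
}

#' @export
print.pawc_population <- function(x, ...) {
  cat("PAWC population quantities [", x$scheme, " weights]\n", sep = "")
  cat(sprintf("  a = %.4f  b = %.4f  c = %.4f  ab = %.4f\n",
              x$a, x$b, x$c, x$ab))
  cat(sprintf("  tau_a = %.4f  tau_b = %.4f  tau_c = %.4f  tau_ab = %.4f\n",
              x$tau_a, x$tau_b, x$tau_c, x$tau_ab))
  invisible(x)
}

#' Least-squares path analysis on composite scores
#'
#' Fits the two path-analysis regressions (with intercepts) by ordinary
#' least squares on an N x 3 matrix of composite scores
#' `(xi_hat, eta1_hat, eta2_hat)`, returning coefficient estimates, their
#' standard errors and z statistics, and the indirect effect
#' \eqn{\hat a\hat b} with the Sobel (delta-method) standard error
#' \eqn{(\hat a^2 se_b^2 + \hat b^2 se_a^2)^{1/2}}. The empirical SNR of a
#' coefficient is \eqn{\hat\tau = z/\sqrt{N}}.
#'
#' @param scores numeric N x 3 matrix from [score_composites()].
#' @return list with `a`, `b`, `c`, `ab`, `se_a`, `se_b`, `se_c`,
#'   `sobel_se`, `z_a`, `z_b`, `z_c`, `z_ab`, `n`.
#' @export
ls_fit_paths <- function(scores) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < 4) stop("at least 4 observations are required")
  if (ncol(scores) != 3) stop("scores must have 3 columns")
  sc <- sweep(scores, 2, colMeans(scores))
  M <- crossprod(sc) / n
  if (M[1, 1] < 1e-14 || M[2, 2] < 1e-14)
    stop("zero variance in a predictor")
  # eta1_hat on xi_hat
  a <- M[1, 2] / M[1, 1]
  rss1 <- (M[2, 2] - a^2 * M[1, 1]) * n
  s2e1 <- rss1 / (n - 2)
  se_a <- sqrt(s2e1 / (n * M[1, 1]))
  # eta2_hat on (eta1_hat, xi_hat)
  S11 <- matrix(c(M[2, 2], M[1, 2], M[1, 2], M[1, 1]), 2, 2)
  det11 <- S11[1, 1] * S11[2, 2] - S11[1, 2]^2
  if (det11 < 1e-14 * S11[1, 1] * S11[2, 2])
    stop("collinear predictors in the second regression")
  s12 <- c(M[2, 3], M[1, 3])
  bc <- solve(S11, s12)
  b <- bc[1]; cc <- bc[2]
  rss2 <- (M[3, 3] - sum(bc * s12)) * n
  s2e2 <- rss2 / (n - 3)
  S11inv <- solve(S11)
  se_b <- sqrt(s2e2 * S11inv[1, 1] / n)
  se_c <- sqrt(s2e2 * S11inv[2, 2] / n)
  ab <- a * b
  sobel_se <- sqrt(a^2 * se_b^2 + b^2 * se_a^2)
  list(a = a, b = b, c = cc, ab = ab,
       se_a = se_a, se_b = se_b, se_c = se_c, sobel_se = sobel_se,
       z_a = a / se_a, z_b = b / se_b, z_c = cc / se_c,
       z_ab = ab / sobel_se, n = n)
}
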
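# SNR of the indirect effect under path analysis with Bartlett-factor
# scores when the weights are estimated from the same sample.
#
# The estimate ab-hat is a smooth function g(S) of the sample covariance
# matrix: S -> NML estimates theta-hat(S) -> Bartlett weights -> composite
# sample moments W'SW -> LS coefficients -> product. Its asymptotic variance
# is obtained by the delta method over vech(S),
#   omega^2 = grad(g)' Gamma grad(g),
# with Gamma the normal-theory asymptotic covariance of sqrt(N) vech(S).
# The estimator map theta-hat(S) enters through its exact first-order
# linearization at S = Sigma(theta),
#   d theta-hat / d vech(S) = (Delta' W Delta)^{-1} Delta' W,
# where Delta = d vech(Sigma)/d theta' and W is the normal-theory weight
# matrix; Delta' W Delta equals the expected information.

vech <- function(M) M[lower.tri(M, diag = TRUE)]

vech_index_pairs <- function(p) {
  idx <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  # arr.ind gives (row, col) in column-major vech order
  idx
}

duplication_matrix <- function(p) {
  ps <- p * (p + 1) / 2
  D <- matrix(0, p * p, ps)
  idx <- vech_index_pairs(p)
  for (u in seq_len(ps)) {
    i <- idx[u, 1]; j <- idx[u, 2]
    D[(j - 1) * p + i, u] <- 1
    D[(i - 1) * p + j, u] <- 1
  }
  D
}

# normal-theory asymptotic covariance of sqrt(N) vech(S):
# Gamma[(i,j),(k,l)] = sigma_ik sigma_jl + sigma_il sigma_jk
gamma_vech_normal <- function(sigma) {
  p <- nrow(sigma)
  idx <- vech_index_pairs(p)
  ps <- nrow(idx)
  G <- matrix(0, ps, ps)
  for (u in seq_len(ps)) {
    i <- idx[u, 1]; j <- idx[u, 2]
    for (v in u:ps) {
      k <- idx[v, 1]; l <- idx[v, 2]
      G[u, v] <- G[v, u] <-
        sigma[i, k] * sigma[j, l] + sigma[i, l] * sigma[j, k]
    }
  }
  G
}

# Path coefficients (a, c, b, ab) with Bartlett weights from theta_w and
# composite moments taken from S. The weights are those of the
# variance-standardized confirmatory factor solution implied by theta_w
# (factor variances fixed at 1), which is how factor scores are computed in
# practice; the data-dependent standardization is part of the estimator and
# is what makes estimated weights usually *reduce* the variance of the
# indirect-effect estimate. `sd_ref` (population factor SDs) rescales the
# coefficients back to the 1-1 link scale so they are comparable, at the
# population point, to the conditional-on-weights quantities; being fixed
# constants, this rescaling leaves every SNR unchanged.
pawc_coef_map <- function(theta_w, S, p = c(3L, 3L, 3L), sd_ref = c(1, 1, 1)) {
  bp <- params_from_theta(theta_w, p, validate = FALSE)
  sd_w <- sqrt(diag(latent_cov(bp)))
  bw <- function(lambda, psi) {
    w <- lambda / psi
    w / sum(w * lambda)
  }
  np <- sum(p)
  W <- matrix(0, np, 3)
  W[seq_len(p[1]), 1] <- bw(bp$lambda_x, bp$psi_x) * sd_ref[1] / sd_w[1]
  W[p[1] + seq_len(p[2]), 2] <- bw(bp$lambda_y1, bp$psi_y1) * sd_ref[2] / sd_w[2]
  W[p[1] + p[2] + seq_len(p[3]), 3] <- bw(bp$lambda_y2, bp$psi_y2) * sd_ref[3] / sd_w[3]
  C <- crossprod(W, S %*% W)
  a <- C[1, 2] / C[1, 1]
  S11 <- matrix(c(C[2, 2], C[1, 2], C[1, 2], C[1, 1]), 2, 2)
  bc <- solve(S11, c(C[2, 3], C[1, 3]))
  c(a = a, c = bc[2], b = bc[1], ab = a * bc[1])
}

#' SNR of PAWC coefficients with estimated Bartlett-factor-score weights
#'
#' Asymptotic variances and SNRs of the path-analysis estimates
#' \eqn{(\hat a, \hat c, \hat b, \hat a\hat b)} when the Bartlett weights
#' are re-estimated from each sample via normal-theory ML, accounting for
#' the sampling error in the estimated weights. The computation is a delta
#' method over the sample covariance matrix: the gradient combines the
#' direct channel (composite moments are functions of S) with the weight
#' channel (weights are functions of the ML estimates, themselves functions
#' of S through the exact first-order linearization of the estimator).
#' Setting `weight_sensitivity = FALSE` zeroes the weight channel and
#' reproduces the conditional-on-weights variances.
#'
#' The weights are those of the variance-standardized confirmatory factor
#' solution (see [bartlett_weights()]); the sampling variation of the fitted
#' factor SDs is part of the weight channel and is what usually makes the
#' estimated-weights SNR exceed the fixed-weights one. Coefficients are
#' reported on the 1-1 link scale via a fixed population rescaling, which
#' leaves all SNRs unchanged.
#'
#' @param bp a [base_params()] object.
#' @param h_rel relative step for the central finite differences on the
#'   coefficient map (the estimator linearization itself is analytic).
#' @param weight_sensitivity logical; include the estimated-weight channel.
#' @return list of class `"snr_estimated_weights"`: `omega2_ab_hat`,
#'   `tau_ab_hat`, per-coefficient `omega2` and `tau` vectors (named
#'   `a`, `c`, `b`, `ab`), `coef` (population values), and `jacobian_norm`.
#' @export
snr_estimated_weights <- function(bp, h_rel = 1e-5, weight_sensitivity = TRUE) {
  validate_base_params(bp)
  p <- unname(block_sizes(bp))
  np <- sum(p)
  theta <- unname(as_theta(bp))
  sigma <- implied_covariance(bp)$sigma
  idx <- vech_index_pairs(np)
  ps <- nrow(idx)

  sd_ref <- sqrt(diag(latent_cov(bp)))
  coef0 <- pawc_coef_map(theta, sigma, p, sd_ref)

  # direct channel: d(coef)/d vech(S), central differences, symmetric steps
  dA_ds <- matrix(0, ps, 4)
  for (u in seq_len(ps)) {
    i <- idx[u, 1]; j <- idx[u, 2]
    h <- h_rel * sqrt(sigma[i, i] * sigma[j, j])
    Sp <- sigma; Sm <- sigma
    Sp[i, j] <- Sp[i, j] + h; Sp[j, i] <- Sp[i, j]
    Sm[i, j] <- Sm[i, j] - h; Sm[j, i] <- Sm[i, j]
    dA_ds[u, ] <- (pawc_coef_map(theta, Sp, p, sd_ref) -
                   pawc_coef_map(theta, Sm, p, sd_ref)) / (2 * h)
  }

  grad <- dA_ds
  if (weight_sensitivity) {
    # weight channel: d(coef)/d theta. Measurement parameters enter through
    # the Bartlett formula; structural parameters through the factor SDs of
    # the variance standardization.
    q <- length(theta)
    dA_dth <- matrix(0, q, 4)
    for (k in seq_len(q)) {
      h <- h_rel * max(abs(theta[k]), 1e-2)
      tp <- theta; tm <- theta
      tp[k] <- tp[k] + h; tm[k] <- tm[k] - h
      dA_dth[k, ] <- (pawc_coef_map(tp, sigma, p, sd_ref) -
                      pawc_coef_map(tm, sigma, p, sd_ref)) / (2 * h)
    }
    # estimator linearization: d theta-hat / d vech(S)
    dsig <- dsigma_sem(theta, p)
    Delta <- vapply(dsig, vech, numeric(ps))          # ps x q
    sinv <- chol2inv(chol(sigma))
    Dp <- duplication_matrix(np)
    Wmat <- 0.5 * crossprod(Dp, (sinv %x% sinv) %*% Dp)
    info <- crossprod(Delta, Wmat %*% Delta)
    J <- solve(info, crossprod(Delta, Wmat))          # q x ps
    grad <- grad + crossprod(J, dA_dth)               # ps x 4
  }

  Gam <- gamma_vech_normal(sigma)
  omega2 <- stats::setNames(colSums(grad * (Gam %*% grad)), names(coef0))
  if (any(omega2 <= 0)) stop("non-positive asymptotic variance")
  tau <- coef0 / sqrt(omega2)
  structure(list(
    omega2_ab_hat = unname(omega2["ab"]),
    tau_ab_hat = unname(tau["ab"]),
    omega2 = omega2,
    tau = tau,
    coef = coef0,
    jacobian_norm = sqrt(sum(grad[, 4]^2)),
    weight_sensitivity = weight_sensitivity),
    class = "snr_estimated_weights")
}

#' @export
print.snr_estimated_weights <- function(x, ...) {
  cat("PAWC SNR with estimated Bartlett weights",
      if (!x$weight_sensitivity) "(weight channel zeroed)", "\n")
  cat(sprintf("  tau_ab = %.4f  (omega_ab = %.4f)\n",
              x$tau_ab_hat, sqrt(x$omega2_ab_hat)))
  cat("  tau:", paste(sprintf("%s %.4f", names(x$tau), x$tau),
                      collapse = "  "), "\n")
  invisible(x)
}
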
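# Normal-theory ML engine for the mediation SEM and the auxiliary
# confirmatory factor model. All information-matrix quantities are per
# observation, so SNRs computed from them are free of the sample size N.

sem_indices <- function(p = c(3L, 3L, 3L)) {
  q <- 2L * sum(p) + 3L
  list(p = p, q = q,
       lam = seq_len(p[1] + p[2] + p[3] - 2L),
       psi = (p[1] + p[2] + p[3] - 2L) + seq_len(sum(p)),
       gamma1 = q - 4L, gamma2 = q - 3L, beta1 = q - 2L,
       szeta1 = q - 1L, szeta2 = q)
}

# rows/factors of the free loadings in theta order
sem_loading_map <- function(p = c(3L, 3L, 3L)) {
  rows <- c(seq_len(p[1]), p[1] + seq_len(p[2])[-1], p[1] + p[2] + seq_len(p[3])[-1])
  fac <- c(rep(1L, p[1]), rep(2L, p[2] - 1L), rep(3L, p[3] - 1L))
  list(rows = rows, fac = fac)
}

sigma_sem <- function(theta, p = c(3L, 3L, 3L), anchors = c(1, 1),
                      sigma2_xi = 1) {
  bp <- params_from_theta(theta, p, anchors = anchors, sigma2_xi = sigma2_xi,
                          validate = FALSE)
  phi <- latent_cov(bp)
  L <- loading_matrix(bp)
  psi <- c(bp$psi_x, bp$psi_y1, bp$psi_y2)
  list(sigma = L %*% phi %*% t(L) + diag(psi), L = L, phi = phi, bp = bp)
}

# derivatives of Phi wrt (gamma1, gamma2, beta1, szeta1, szeta2)
dphi_sem <- function(bp) {
  s <- bp$sigma2_xi
  g1 <- bp$gamma1; g2 <- bp$gamma2; b1 <- bp$beta1
  s2e1 <- g1^2 * s + bp$sigma2_zeta1
  d <- list()
  d$gamma1 <- matrix(c(0, s, b1 * s,
                       s, 2 * g1 * s, 2 * b1 * g1 * s + g2 * s,
                       b1 * s, 2 * b1 * g1 * s + g2 * s,
                       2 * b1^2 * g1 * s + 2 * b1 * g2 * s), 3, 3)
  d$gamma2 <- matrix(c(0, 0, s,
                       0, 0, g1 * s,
                       s, g1 * s, 2 * g2 * s + 2 * b1 * g1 * s), 3, 3)
  d$beta1 <- matrix(c(0, 0, g1 * s,
                      0, 0, s2e1,
                      g1 * s, s2e1, 2 * b1 * s2e1 + 2 * g2 * g1 * s), 3, 3)
  d$szeta1 <- matrix(c(0, 0, 0,
                       0, 1, b1,
                       0, b1, b1^2), 3, 3)
  d$szeta2 <- matrix(c(0, 0, 0, 0, 0, 0, 0, 0, 1), 3, 3)
  d
}

# full list of dSigma/dtheta_j matrices in theta order
dsigma_sem <- function(theta, p = c(3L, 3L, 3L), anchors = c(1, 1),
                       sigma2_xi = 1) {
  ss <- sigma_sem(theta, p, anchors, sigma2_xi)
  L <- ss$L; phi <- ss$phi
  G <- L %*% phi
  np <- sum(p)
  lm <- sem_loading_map(p)
  out <- vector("list", length(theta))
  k <- 0L
  for (j in seq_along(lm$rows)) {
    k <- k + 1L
    M <- matrix(0, np, np)
    M[lm$rows[j], ] <- G[, lm$fac[j]]
    out[[k]] <- M + t(M)
  }
  for (i in seq_len(np)) {
    k <- k + 1L
    M <- matrix(0, np, np)
    M[i, i] <- 1
    out[[k]] <- M
  }
  for (dphi in dphi_sem(ss$bp)) {
    k <- k + 1L
    out[[k]] <- L %*% dphi %*% t(L)
  }
  out
}

information_from_dsigma <- function(sigma, dsig) {
  q <- length(dsig)
  sinv <- chol2inv(chol(sigma))
  A <- lapply(dsig, function(d) sinv %*% d)
  info <- matrix(0, q, q)
  for (j in seq_len(q)) {
    tAj <- t(A[[j]])
    for (k in j:q) {
      info[j, k] <- info[k, j] <- 0.5 * sum(tAj * A[[k]])
    }
  }
  info
}

#' Expected information matrix of the mediation SEM
#'
#' Normal-theory expected (Fisher) information per observation for the free
#' parameters, \eqn{I_{jk} = \frac{1}{2} tr(\Sigma^{-1}\dot\Sigma_j
#' \Sigma^{-1}\dot\Sigma_k)}, evaluated at the supplied parameter values.
#' Its inverse is the asymptotic covariance matrix of
#' \eqn{\sqrt{N}\,\hat\theta} under normal-theory maximum likelihood.
#'
#' @param bp a [base_params()] object.
#' @return a symmetric positive definite q x q matrix with the
#'   free-parameter names of [as_theta()].
#' @export
expected_information <- function(bp) {
  validate_base_params(bp)
  theta <- as_theta(bp)
  p <- unname(block_sizes(bp))
  anchors <- c(bp$lambda_y1[1], bp$lambda_y2[1])
  ss <- sigma_sem(theta, p, anchors, bp$sigma2_xi)
  info <- information_from_dsigma(
    ss$sigma, dsigma_sem(theta, p, anchors, bp$sigma2_xi))
  dimnames(info) <- list(names(theta), names(theta))
  info
}

#' Population SNR of the structural estimates under SEM
#'
#' Computes the population (asymptotic) signal-to-noise ratios of the
#' normal-theory ML estimates of \eqn{\gamma_1}, \eqn{\gamma_2},
#' \eqn{\beta_1} and the indirect effect \eqn{\gamma_1\beta_1}. Writing
#' \eqn{V = I(\theta)^{-1}} for the asymptotic covariance of
#' \eqn{\sqrt{N}\hat\theta} and \eqn{(v_{gg}, v_{bb}, v_{gb})} for the block
#' of \eqn{(\hat\gamma_1, \hat\beta_1)}, the delta-method SD of
#' \eqn{\sqrt{N}\hat\gamma_1\hat\beta_1} is
#' \deqn{\omega_{\gamma_1\beta_1} = (\beta_1^2 v_{gg} + \gamma_1^2 v_{bb}
#'   + 2\beta_1\gamma_1 v_{gb})^{1/2},}
#' and the SNR is \eqn{\tau_{\gamma_1\beta_1} =
#' \gamma_1\beta_1/\omega_{\gamma_1\beta_1}}. All quantities are free of N
#' and invariant to the latent-variable scaling.
#'
#' @param bp a [base_params()] object.
#' @return list of class `"snr_sem"`: `tau_gamma1`, `tau_gamma2`,
#'   `tau_beta1`, `tau_indirect`, `omega_indirect`, and the 2x2 block `V`.
#' @export
population_snr_sem <- function(bp) {
  info <- expected_information(bp)
  ch <- tryCatch(chol(info), error = function(e) NULL)
  if (is.null(ch)) {
    ev <- eigen(info, symmetric = TRUE, only.values = TRUE)$values
    stop("expected information is singular (smallest eigenvalue ",
         format(min(ev)), ")")
  }
  V <- chol2inv(ch)
  dimnames(V) <- dimnames(info)
  idx <- sem_indices(unname(block_sizes(bp)))
  vgg <- V[idx$gamma1, idx$gamma1]
  vbb <- V[idx$beta1, idx$beta1]
  vgb <- V[idx$gamma1, idx$beta1]
  g1 <- bp$gamma1; b1 <- bp$beta1
  omega <- sqrt(b1^2 * vgg + g1^2 * vbb + 2 * b1 * g1 * vgb)
  structure(list(
    tau_gamma1 = g1 / sqrt(vgg),
    tau_gamma2 = bp$gamma2 / sqrt(V[idx$gamma2, idx$gamma2]),
    tau_beta1 = b1 / sqrt(vbb),
    tau_indirect = g1 * b1 / omega,
    omega_indirect = omega,
    V = matrix(c(vgg, vgb, vgb, vbb), 2, 2,
               dimnames = list(c("gamma1", "beta1"), c("gamma1", "beta1")))),
    class = "snr_sem")
}

#' @export
print.snr_sem <- function(x, ...) {
  cat("Population SNR under SEM\n")
  cat(sprintf("  tau(gamma1) = %.4f  tau(gamma2) = %.4f  tau(beta1) = %.4f\n",
              x$tau_gamma1, x$tau_gamma2, x$tau_beta1))
  cat(sprintf("  tau(gamma1*beta1) = %.4f  (omega = %.4f)\n",
              x$tau_indirect, x$omega_indirect))
  invisible(x)
}

# ---- confirmatory factor model (3 correlated factors, variances fixed at 1)

cfa_names <- function(p = c(3L, 3L, 3L)) {
  c(paste0("l", seq_len(sum(p))),
    paste0("psi", seq_len(sum(p))),
    "phi21", "phi31", "phi32")
}

sigma_cfa <- function(theta, p = c(3L, 3L, 3L)) {
  np <- sum(p)
  lam <- theta[seq_len(np)]
  psi <- theta[np + seq_len(np)]
  ph <- theta[2L * np + 1:3]
  phi <- matrix(c(1, ph[1], ph[2], ph[1], 1, ph[3], ph[2], ph[3], 1), 3, 3)
  L <- matrix(0, np, 3)
  L[seq_len(p[1]), 1] <- lam[seq_len(p[1])]
  L[p[1] + seq_len(p[2]), 2] <- lam[p[1] + seq_len(p[2])]
  L[p[1] + p[2] + seq_len(p[3]), 3] <- lam[p[1] + p[2] + seq_len(p[3])]
  list(sigma = L %*% phi %*% t(L) + diag(psi), L = L, phi = phi)
}

dsigma_cfa <- function(theta, p = c(3L, 3L, 3L)) {
  ss <- sigma_cfa(theta, p)
  L <- ss$L; phi <- ss$phi
  G <- L %*% phi
  np <- sum(p)
  fac <- rep(1:3, p)
  out <- vector("list", length(theta))
  k <- 0L
  for (i in seq_len(np)) {
    k <- k + 1L
    M <- matrix(0, np, np)
    M[i, ] <- G[, fac[i]]
    out[[k]] <- M + t(M)
  }
  for (i in seq_len(np)) {
    k <- k + 1L
    M <- matrix(0, np, np)
    M[i, i] <- 1
    out[[k]] <- M
  }
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    k <- k + 1L
    M <- tcrossprod(L[, pair[1]], L[, pair[2]])
    out[[k]] <- M + t(M)
  }
  out
}

# ---- ML discrepancy minimization

fml_value <- function(sigma, S, logdetS) {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  sinv <- chol2inv(ch)
  sum(S * sinv) + 2 * sum(log(diag(ch))) - logdetS - nrow(S)
}

default_start_sem <- function(S, p = c(3L, 3L, 3L)) {
  np <- sum(p)
  # equally weighted composite path analysis supplies the structural starts
  W <- matrix(0, np, 3)
  W[seq_len(p[1]), 1] <- 1 / p[1]
  W[p[1] + seq_len(p[2]), 2] <- 1 / p[2]
  W[p[1] + p[2] + seq_len(p[3]), 3] <- 1 / p[3]
  C <- crossprod(W, S %*% W)
  a0 <- C[1, 2] / C[1, 1]
  bc <- tryCatch(solve(matrix(c(C[2, 2], C[1, 2], C[1, 2], C[1, 1]), 2, 2),
                       c(C[2, 3], C[1, 3])),
                 error = function(e) c(0.3, 0.3))
  th <- c(rep(1, np - 2L), pmax(diag(S) / 2, 0.05),
          a0, bc[2], bc[1], 0.5, 0.5)
  stats::setNames(th, theta_names(p))
}

default_start_cfa <- function(S, p = c(3L, 3L, 3L)) {
  stats::setNames(c(sqrt(pmax(diag(S) / 2, 0.05)), pmax(diag(S) / 2, 0.05),
                    0.3, 0.3, 0.3), cfa_names(p))
}

#' Fit the mediation SEM (or auxiliary CFA) by normal-theory ML
#'
#' Minimizes the ML discrepancy
#' \deqn{F_{ML}(\theta) = tr(S\Sigma^{-1}) - \log|S\Sigma^{-1}| - p}
#' over the free parameters using a quasi-Newton method with the analytic
#' gradient, with error/residual variances bounded below to keep
#' \eqn{\Sigma(\theta)} positive definite. `model = "sem"` fits the
#' three-factor mediation model of [base_params()]; `model = "cfa"` fits the
#' statistically equivalent confirmatory factor model with all loadings free,
#' factor variances fixed at 1 and freely correlated factors (the
#' parameterization conventional for covariance-matrix input).
#'
#' @param S p x p sample covariance matrix (divisor-N convention assumed for
#'   the likelihood-ratio statistic).
#' @param N sample size used to compute `test_stat = (N - 1) * fmin` and SEs.
#' @param start optional start values: a [base_params()] object or named
#'   theta vector. Defaults to unit loadings, half-variance errors, and
#'   structural starts from an equally-weighted-composite path analysis.
#' @param model `"sem"` or `"cfa"`.
#' @param p indicators per block.
#' @param se logical; compute the inverse-information covariance matrix.
#' @param control list passed to [stats::nlminb()].
#' @return An object of class `"sem_fit"`: `theta_hat`, `params`
#'   (a [base_params()], `model = "sem"` only), `vcov` (covariance of
#'   \eqn{\sqrt{N}\hat\theta}), `fmin`, `converged`, `heywood`, `n_iter`,
#'   `test_stat`, `df`, `N`, `model`.
#' @examples
#' bp <- params_from_theta(rep(0.6, 21))
#' fit <- nml_fit(implied_covariance(bp)$sigma, N = 500, start = bp)
#' fit$fmin   # ~0: zero-discrepancy recovery
#' @export
nml_fit <- function(S, N, start = NULL, model = c("sem", "cfa"),
                    p = c(3L, 3L, 3L), se = TRUE, control = list()) {
  model <- match.arg(model)
  S <- as.matrix(S)
  np <- sum(p)
  if (nrow(S) != np || ncol(S) != np) stop("S must be ", np, " x ", np)
  if (max(abs(S - t(S))) > 1e-8) stop("S must be symmetric")
  chS <- tryCatch(chol(S), error = function(e)
    stop("S must be positive definite"))
  logdetS <- 2 * sum(log(diag(chS)))
  if (model == "sem") {
    q <- 2L * sum(p) + 3L
    if (N <= q) stop("N must exceed the number of free parameters (", q, ")")
    sig_fn <- function(th) sigma_sem(th, p)
    dsig_fn <- function(th) dsigma_sem(th, p)
    idx <- sem_indices(p)
    lower <- rep(-Inf, q)
    lower[c(idx$psi, idx$szeta1, idx$szeta2)] <- 1e-6
    var_idx <- c(idx$psi, idx$szeta1, idx$szeta2)
    th0 <- if (is.null(start)) default_start_sem(S, p)
           else if (inherits(start, "base_params")) as_theta(start)
           else stats::setNames(as.numeric(start), theta_names(p))
  } else {
    q <- 2L * np + 3L
    sig_fn <- function(th) sigma_cfa(th, p)
    dsig_fn <- function(th) dsigma_cfa(th, p)
    lower <- c(rep(-Inf, np), rep(1e-6, np), rep(-0.999, 3))
    var_idx <- np + seq_len(np)
    th0 <- if (is.null(start)) default_start_cfa(S, p)
           else stats::setNames(as.numeric(start), cfa_names(p))
  }
  upper <- rep(Inf, q)
  if (model == "cfa") upper[2L * np + 1:3] <- 0.999

  cache <- new.env(parent = emptyenv())
  eval_at <- function(th) {
    if (!is.null(cache$th) && identical(cache$th, th)) return(cache$val)
    ss <- sig_fn(th)
    ch <- tryCatch(chol(ss$sigma), error = function(e) NULL)
    val <- if (is.null(ch)) {
      list(bad = TRUE, f = 1e10, grad = rep(0, q))
    } else {
      sinv <- chol2inv(ch)
      f <- sum(S * sinv) + 2 * sum(log(diag(ch))) - logdetS - np
      M <- sinv - sinv %*% S %*% sinv
      grad <- vapply(dsig_fn(th), function(d) sum(M * d), numeric(1))
      list(bad = FALSE, f = f, grad = grad)
    }
    cache$th <- th
    cache$val <- val
    val
  }
  obj <- function(th) eval_at(th)$f
  gr <- function(th) eval_at(th)$grad
  ctrl <- utils::modifyList(list(iter.max = 500L, eval.max = 1000L), control)
  res <- stats::nlminb(th0, obj, gradient = gr, lower = lower, upper = upper,
                       control = ctrl)
  theta_hat <- stats::setNames(res$par, names(th0))
  heywood <- any(theta_hat[var_idx] <= 2e-6)
  converged <- res$convergence == 0 && is.finite(res$objective) &&
    res$objective < 1e9
  vcov <- NULL
  if (se && converged) {
    ss <- sig_fn(theta_hat)
    info <- information_from_dsigma(ss$sigma, dsig_fn(theta_hat))
    dimnames(info) <- list(names(theta_hat), names(theta_hat))
    vcov <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
    if (!is.null(vcov)) dimnames(vcov) <- dimnames(info)
  }
  df <- np * (np + 1L) / 2L - q
  structure(list(
    theta_hat = theta_hat,
    params = if (model == "sem")
      params_from_theta(unname(theta_hat), p, validate = FALSE) else NULL,
    vcov = vcov,
    fmin = res$objective,
    converged = converged,
    heywood = heywood,
    n_iter = res$iterations,
    test_stat = (N - 1) * res$objective,
    df = df, N = N, model = model, p = p,
    message = res$message),
    class = "sem_fit")
}

#' @export
print.sem_fit <- function(x, ...) {
  cat("Normal-theory ML fit (", x$model, "), N = ", x$N, "\n", sep = "")
  cat(sprintf("  F_ml = %.6f  T_ml = %.3f on df = %d\n",
              x$fmin, x$test_stat, x$df))
  cat("  converged:", x$converged,
      if (x$heywood) " [Heywood: variance at boundary]" else "", "\n")
  invisible(x)
}

#' Delta-method inference for the indirect effect from a fitted SEM
#'
#' Computes the estimate \eqn{\hat\gamma_1\hat\beta_1}, its delta-method
#' standard error
#' \eqn{SE = (\hat\beta_1^2 v_{gg} + \hat\gamma_1^2 v_{bb} +
#' 2\hat\beta_1\hat\gamma_1 v_{gb})^{1/2}/\sqrt{N}},
#' and the z statistic. The empirical SNR can be recovered as
#' \eqn{\hat\tau = z/\sqrt{N}}.
#'
#' @param fit a converged `"sem_fit"` with `model = "sem"` and `se = TRUE`.
#' @return list with `estimate`, `se`, `z`.
#' @export
indirect_se_delta <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  if (fit$model != "sem") stop("indirect effect is defined for model = 'sem'")
  if (!fit$converged || is.null(fit$vcov))
    stop("fit did not converge or has no covariance matrix")
  idx <- sem_indices(fit$p)
  g1 <- fit$theta_hat[idx$gamma1]
  b1 <- fit$theta_hat[idx$beta1]
  vgg <- fit$vcov[idx$gamma1, idx$gamma1]
  vbb <- fit$vcov[idx$beta1, idx$beta1]
  vgb <- fit$vcov[idx$gamma1, idx$beta1]
  se <- sqrt(b1^2 * vgg + g1^2 * vbb + 2 * b1 * g1 * vgb) / sqrt(fit$N)
  list(estimate = unname(g1 * b1), se = unname(se),
       z = unname(g1 * b1 / se))
}
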
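# Weighted composites of the indicator blocks: Bartlett-factor scores,
# equally weighted composites, and their reliabilities.

#' Reliability of a weighted composite
#'
#' For a congeneric block \eqn{y = \lambda f + e} with \eqn{Var(f) =
#' \sigma^2_f} and \eqn{Cov(e) = diag(\psi)}, the reliability of the
#' composite \eqn{w'y} is the proportion of its variance due to the factor:
#' \deqn{\rho = \frac{(w'\lambda)^2 \sigma^2_f}
#'   {(w'\lambda)^2 \sigma^2_f + w' diag(\psi) w}.}
#' It is invariant to rescaling of `w`. After the normalization
#' \eqn{w'\lambda = 1} the composite variance equals \eqn{\sigma^2_f/\rho}.
#'
#' @param w weight vector.
#' @param lambda factor loadings of the block.
#' @param psi measurement-error variances of the block (>= 0).
#' @param sigma2_f variance of the factor.
#' @return reliability in (0, 1].
#' @export
composite_reliability <- function(w, lambda, psi, sigma2_f = 1) {
  stopifnot(length(w) == length(lambda), length(psi) == length(lambda),
            all(psi >= 0), sigma2_f > 0)
  wl <- sum(w * lambda)
  if (abs(wl) < 1e-12)
    stop("w'lambda = 0: composite carries no factor signal")
  true_var <- wl^2 * sigma2_f
  true_var / (true_var + sum(w^2 * psi))
}

new_composite_spec <- function(scheme, w_x, w_y1, w_y2,
                               rho_xi, rho_eta1, rho_eta2, source) {
  structure(list(scheme = scheme,
                 w_x = w_x, w_y1 = w_y1, w_y2 = w_y2,
                 rho_xi = rho_xi, rho_eta1 = rho_eta1, rho_eta2 = rho_eta2,
                 source = source),
            class = "composite_spec")
}

#' Construct a composite weighting scheme
#'
#' Low-level constructor for a `"composite_spec"`: per-block weight vectors
#' with their reliabilities. Weights are normalized so that
#' \eqn{w'\lambda = 1} per block (the "1-1 link": the composite equals the
#' factor plus an uncorrelated error, so its regression slope on the factor
#' is one). When `theta` is supplied, reliabilities are computed from it via
#' [composite_reliability()]; otherwise they must be given explicitly (useful
#' for analyzing limiting cases such as error-free composites).
#'
#' @param w_x,w_y1,w_y2 raw weight vectors per block.
#' @param theta optional [base_params()] used to normalize weights and
#'   compute reliabilities.
#' @param rho explicit reliabilities `c(rho_xi, rho_eta1, rho_eta2)`,
#'   required when `theta` is missing.
#' @param scheme label, default `"user"`.
#' @param source `"population"` or `"estimated"`.
#' @return a `"composite_spec"`.
#' @seealso [bartlett_weights()], [equal_weights()]
#' @export
composite_spec <- function(w_x, w_y1, w_y2, theta = NULL, rho = NULL,
                           scheme = "user", source = "population") {
  if (!is.null(theta)) {
    stopifnot(inherits(theta, "base_params"))
    mom <- implied_covariance(theta)
    w_x <- w_x / sum(w_x * theta$lambda_x)
    w_y1 <- w_y1 / sum(w_y1 * theta$lambda_y1)
    w_y2 <- w_y2 / sum(w_y2 * theta$lambda_y2)
    rho <- c(
      composite_reliability(w_x, theta$lambda_x, theta$psi_x, theta$sigma2_xi),
      composite_reliability(w_y1, theta$lambda_y1, theta$psi_y1, mom$sigma2_eta1),
      composite_reliability(w_y2, theta$lambda_y2, theta$psi_y2, mom$sigma2_eta2))
  } else if (is.null(rho)) {
    stop("either theta or explicit rho values must be supplied")
  }
  if (any(rho <= 0 | rho > 1)) stop("reliabilities must lie in (0, 1]")
  new_composite_spec(scheme, w_x, w_y1, w_y2, rho[1], rho[2], rho[3], source)
}

#' Bartlett-factor-score weights
#'
#' Per block, the Bartlett (maximum-likelihood) factor-score weights are
#' proportional to \eqn{\Psi^{-1}\lambda}; with the independent-cluster
#' loading structure of the mediation model the joint Bartlett transform
#' \eqn{(\Lambda'\Psi^{-1}\Lambda)^{-1}\Lambda'\Psi^{-1}} reduces to these
#' per-block weights. They maximize the composite reliability and give
#' conditionally unbiased factor scores.
#'
#' Population weights are normalized to \eqn{w'\lambda = 1} (the 1-1 link
#' with the latent variable). Estimated weights, computed from a fitted
#' model, are those of the variance-standardized confirmatory factor
#' solution (factor variances fixed at 1, i.e. the normalized weights
#' further divided by the fitted factor SDs), which is how factor scores
#' are computed in practice. The distinction is irrelevant for any SNR
#' conditional on weights, but the data-dependent standardization is part
#' of the estimated-weights estimator and affects — usually reduces — the
#' sampling variance of the indirect-effect estimate.
#'
#' @param x a [base_params()] object (population weights) or a converged
#'   `"sem_fit"` with `model = "sem"` (estimated weights, computed from the
#'   fitted loadings and error variances).
#' @return a `"composite_spec"` with `scheme = "bartlett"`.
#' @export
bartlett_weights <- function(x) {
  if (inherits(x, "sem_fit")) {
    if (is.null(x$params)) stop("fit does not carry mediation-model parameters")
    bp <- x$params
    src <- "estimated"
  } else {
    bp <- x
    src <- "population"
  }
  stopifnot(inherits(bp, "base_params"))
  if (any(c(bp$psi_x, bp$psi_y1, bp$psi_y2) <= 0))
    stop("Bartlett weights are degenerate with non-positive error variances")
  mom <- implied_covariance(bp)
  bw <- function(lambda, psi) {
    w <- lambda / psi
    w / sum(w * lambda)
  }
  w_x <- bw(bp$lambda_x, bp$psi_x)
  w_y1 <- bw(bp$lambda_y1, bp$psi_y1)
  w_y2 <- bw(bp$lambda_y2, bp$psi_y2)
  if (src == "estimated") {
    sd_f <- sqrt(diag(latent_cov(bp)))
    w_x <- w_x / sd_f[1]; w_y1 <- w_y1 / sd_f[2]; w_y2 <- w_y2 / sd_f[3]
  }
  new_composite_spec(
    "bartlett", w_x, w_y1, w_y2,
    composite_reliability(w_x, bp$lambda_x, bp$psi_x, bp$sigma2_xi),
    composite_reliability(w_y1, bp$lambda_y1, bp$psi_y1, mom$sigma2_eta1),
    composite_reliability(w_y2, bp$lambda_y2, bp$psi_y2, mom$sigma2_eta2),
    src)
}

#' Equally weighted composites
#'
#' All indicators of a block get the same raw weight, then weights are
#' normalized to \eqn{w'\lambda = 1}. This is the sum/average score; its
#' reliability never exceeds the Bartlett-factor-score reliability of the
#' same block.
#'
#' @param bp a [base_params()] object.
#' @return a `"composite_spec"` with `scheme = "equal"`.
#' @export
equal_weights <- function(bp) {
  stopifnot(inherits(bp, "base_params"))
  composite_spec(rep(1, length(bp$lambda_x)),
                 rep(1, length(bp$lambda_y1)),
                 rep(1, length(bp$lambda_y2)),
                 theta = bp, scheme = "equal")
}

#' @export
print.composite_spec <- function(x, ...) {
  cat("Composite spec [", x$scheme, ", ", x$source, " weights]\n", sep = "")
  cat("  w_x :", format(x$w_x, digits = 3), "\n")
  cat("  w_y1:", format(x$w_y1, digits = 3), "\n")
  cat("  w_y2:", format(x$w_y2, digits = 3), "\n")
  cat(sprintf("  rho: xi-hat %.3f, eta1-hat %.3f, eta2-hat %.3f\n",
              x$rho_xi, x$rho_eta1, x$rho_eta2))
  invisible(x)
}

# 9 x 3 (or p x 3) block weight matrix with normalized weights
weight_matrix <- function(spec) {
  p <- c(length(spec$w_x), length(spec$w_y1), length(spec$w_y2))
  W <- matrix(0, sum(p), 3,
              dimnames = list(NULL, c("xi_hat", "eta1_hat", "eta2_hat")))
  W[seq_len(p[1]), 1] <- spec$w_x
  W[p[1] + seq_len(p[2]), 2] <- spec$w_y1
  W[p[1] + p[2] + seq_len(p[3]), 3] <- spec$w_y2
  W
}

#' Score composites from indicator data
#'
#' Applies the normalized per-block weights to an N x p data matrix whose
#' columns follow the block layout (x block, then y1, then y2).
#'
#' @param data numeric matrix, N x p.
#' @param spec a `"composite_spec"`.
#' @return N x 3 matrix of scores `(xi_hat, eta1_hat, eta2_hat)`.
#' @export
score_composites <- function(data, spec) {
  stopifnot(inherits(spec, "composite_spec"))
  W <- weight_matrix(spec)
  data <- as.matrix(data)
  if (ncol(data) != nrow(W))
    stop("data has ", ncol(data), " columns; spec expects ", nrow(W))
  data %*% W
}
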
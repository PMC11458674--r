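#' Base parameters of the three-factor mediation model
#'
#' Constructs and validates the parameter vector of the latent-variable
#' mediation model
#' \deqn{x = \lambda_x \xi + e_x, \quad y_1 = \lambda_{y_1}\eta_1 + e_{y_1},
#'       \quad y_2 = \lambda_{y_2}\eta_2 + e_{y_2},}
#' \deqn{\eta_1 = \gamma_1 \xi + \zeta_1, \quad
#'       \eta_2 = \beta_1 \eta_1 + \gamma_2 \xi + \zeta_2.}
#' The model is identified by fixing \eqn{Var(\xi) = 1} and the first
#' loadings of \eqn{\eta_1} and \eqn{\eta_2} at 1.0 (the "anchor" indicators),
#' giving \eqn{q = 2(p_x + p_{y_1} + p_{y_2}) + 3} free parameters
#' (21 when each factor has three indicators).
#'
#' @param lambda_x loadings of the \eqn{\xi} indicators (all free).
#' @param lambda_y1,lambda_y2 loadings of the \eqn{\eta_1}/\eqn{\eta_2}
#'   indicators, *including* the anchor as the first element (fixed, 1.0 by
#'   default).
#' @param psi_x,psi_y1,psi_y2 measurement-error variances per block
#'   (diagonal of the \eqn{\Psi} blocks), all strictly positive.
#' @param gamma1 structural coefficient \eqn{\xi \to \eta_1}.
#' @param gamma2 structural coefficient \eqn{\xi \to \eta_2}.
#' @param beta1 structural coefficient \eqn{\eta_1 \to \eta_2}.
#' @param sigma2_zeta1,sigma2_zeta2 residual variances of \eqn{\eta_1},
#'   \eqn{\eta_2}, strictly positive.
#' @param sigma2_xi variance of \eqn{\xi}; fixed at 1.0 under the default
#'   identification but kept explicit.
#' @return An object of class `"base_params"`.
#' @seealso [implied_covariance()], [generate_conditions()], [as_theta()]
#' @examples
#' bp <- base_params(lambda_x = c(0.8, 0.7, 0.9),
#'                   lambda_y1 = c(1, 0.6, 0.7), lambda_y2 = c(1, 0.8, 0.5),
#'                   psi_x = c(0.5, 0.4, 0.3), psi_y1 = c(0.4, 0.5, 0.6),
#'                   psi_y2 = c(0.3, 0.4, 0.5),
#'                   gamma1 = 0.5, gamma2 = 0.3, beta1 = 0.4,
#'                   sigma2_zeta1 = 0.6, sigma2_zeta2 = 0.7)
#' implied_covariance(bp)$sigma2_eta1
#' @export
base_params <- function(lambda_x, lambda_y1, lambda_y2,
                        psi_x, psi_y1, psi_y2,
                        gamma1, gamma2, beta1,
                        sigma2_zeta1, sigma2_zeta2,
                        sigma2_xi = 1.0) {
  bp <- structure(
    list(lambda_x = as.numeric(lambda_x),
         lambda_y1 = as.numeric(lambda_y1),
         lambda_y2 = as.numeric(lambda_y2),
         psi_x = as.numeric(psi_x),
         psi_y1 = as.numeric(psi_y1),
         psi_y2 = as.numeric(psi_y2),
         gamma1 = as.numeric(gamma1),
         gamma2 = as.numeric(gamma2),
         beta1 = as.numeric(beta1),
         sigma2_zeta1 = as.numeric(sigma2_zeta1),
         sigma2_zeta2 = as.numeric(sigma2_zeta2),
         sigma2_xi = as.numeric(sigma2_xi)),
    class = "base_params")
  validate_base_params(bp)
  bp
}

validate_base_params <- function(bp) {
  stopifnot(inherits(bp, "base_params"))
  if (length(bp$lambda_x) != length(bp$psi_x) ||
      length(bp$lambda_y1) != length(bp$psi_y1) ||
      length(bp$lambda_y2) != length(bp$psi_y2))
    stop("loading and error-variance vectors must have matching lengths per block")
  vars <- c(psi_x = bp$psi_x, psi_y1 = bp$psi_y1, psi_y2 = bp$psi_y2,
            sigma2_zeta1 = bp$sigma2_zeta1, sigma2_zeta2 = bp$sigma2_zeta2,
            sigma2_xi = bp$sigma2_xi)
  bad <- which(!is.finite(vars) | vars <= 0)
  if (length(bad))
    stop("variance parameter not strictly positive: ",
         paste(names(vars)[bad], collapse = ", "))
  scalars <- c(bp$gamma1, bp$gamma2, bp$beta1,
               bp$lambda_x, bp$lambda_y1, bp$lambda_y2)
  if (any(!is.finite(scalars))) stop("non-finite parameter value")
  invisible(bp)
}

#' @export
print.base_params <- function(x, ...) {
  cat("Mediation model base parameters (q =", n_free_params(x), "free)\n")
  cat("  lambda_x :", format(x$lambda_x, digits = 3), "\n")
  cat("  lambda_y1:", format(x$lambda_y1, digits = 3), "(anchor first)\n")
  cat("  lambda_y2:", format(x$lambda_y2, digits = 3), "(anchor first)\n")
  cat("  gamma1 =", format(x$gamma1, digits = 3),
      " gamma2 =", format(x$gamma2, digits = 3),
      " beta1 =", format(x$beta1, digits = 3), "\n")
  cat("  sigma2_zeta1 =", format(x$sigma2_zeta1, digits = 3),
      " sigma2_zeta2 =", format(x$sigma2_zeta2, digits = 3),
      " sigma2_xi =", format(x$sigma2_xi, digits = 3), "\n")
  invisible(x)
}

n_free_params <- function(bp) {
  2L * (length(bp$lambda_x) + length(bp$lambda_y1) + length(bp$lambda_y2)) + 3L
}

block_sizes <- function(bp) {
  c(p_x = length(bp$lambda_x), p_y1 = length(bp$lambda_y1),
    p_y2 = length(bp$lambda_y2))
}

theta_names <- function(p = c(3L, 3L, 3L)) {
  c(paste0("lx", seq_len(p[1])),
    paste0("ly1_", seq_len(p[2])[-1]),
    paste0("ly2_", seq_len(p[3])[-1]),
    paste0("psi_x", seq_len(p[1])),
    paste0("psi_y1_", seq_len(p[2])),
    paste0("psi_y2_", seq_len(p[3])),
    "gamma1", "gamma2", "beta1", "sigma2_zeta1", "sigma2_zeta2")
}

#' Map between base parameters and the free-parameter vector
#'
#' The free parameters are laid out in the fixed order used throughout the
#' package, in condition files, and in the information matrix:
#' `lambda_x` (all), free loadings of `lambda_y1` (2nd onward), free loadings
#' of `lambda_y2`, `psi_x`, `psi_y1`, `psi_y2`, `gamma1`, `gamma2`, `beta1`,
#' `sigma2_zeta1`, `sigma2_zeta2`. Anchor loadings and `sigma2_xi` are fixed
#' and not part of the vector.
#'
#' @param bp a [base_params()] object.
#' @param theta numeric vector of free parameters in the documented order.
#' @param p integer vector of indicators per block, default `c(3, 3, 3)`.
#' @param anchors,sigma2_xi fixed identification values.
#' @param validate logical; check invariants on the result.
#' @return `as_theta()` a named numeric vector; `params_from_theta()` a
#'   [base_params()] object.
#' @export
as_theta <- function(bp) {
  p <- block_sizes(bp)
  stats::setNames(
    c(bp$lambda_x, bp$lambda_y1[-1], bp$lambda_y2[-1],
      bp$psi_x, bp$psi_y1, bp$psi_y2,
      bp$gamma1, bp$gamma2, bp$beta1, bp$sigma2_zeta1, bp$sigma2_zeta2),
    theta_names(p))
}

#' @rdname as_theta
#' @export
params_from_theta <- function(theta, p = c(3L, 3L, 3L),
                              anchors = c(1, 1), sigma2_xi = 1,
                              validate = TRUE) {
  q <- 2L * sum(p) + 3L
  if (length(theta) != q)
    stop("theta must have length ", q, " for p = (", paste(p, collapse = ","),
         "); got ", length(theta))
  i <- 0L
  take <- function(k) { out <- theta[i + seq_len(k)]; i <<- i + k; out }
  bp <- structure(
    list(lambda_x = unname(take(p[1])),
         lambda_y1 = c(anchors[1], unname(take(p[2] - 1L))),
         lambda_y2 = c(anchors[2], unname(take(p[3] - 1L))),
         psi_x = unname(take(p[1])),
         psi_y1 = unname(take(p[2])),
         psi_y2 = unname(take(p[3])),
         gamma1 = unname(take(1L)), gamma2 = unname(take(1L)),
         beta1 = unname(take(1L)),
         sigma2_zeta1 = unname(take(1L)), sigma2_zeta2 = unname(take(1L)),
         sigma2_xi = sigma2_xi),
    class = "base_params")
  if (validate) validate_base_params(bp)
  bp
}

#' Covariance matrix of the latent variables
#'
#' Covariance matrix of \eqn{(\xi, \eta_1, \eta_2)} implied by the structural
#' equations: \eqn{Cov(\xi,\eta_1) = \gamma_1\sigma^2_\xi},
#' \eqn{Cov(\xi,\eta_2) = (\beta_1\gamma_1+\gamma_2)\sigma^2_\xi},
#' \eqn{Cov(\eta_1,\eta_2) = \beta_1\sigma^2_{\eta_1} +
#' \gamma_1\gamma_2\sigma^2_\xi}.
#'
#' @param bp a [base_params()] object.
#' @return symmetric 3x3 matrix with dimnames `xi`, `eta1`, `eta2`.
#' @export
latent_cov <- function(bp) {
  s2xi <- bp$sigma2_xi
  g1 <- bp$gamma1; g2 <- bp$gamma2; b1 <- bp$beta1
  s2e1 <- g1^2 * s2xi + bp$sigma2_zeta1
  s2e2 <- b1^2 * s2e1 + g2^2 * s2xi + 2 * b1 * g2 * g1 * s2xi + bp$sigma2_zeta2
  phi <- matrix(c(s2xi, g1 * s2xi, (b1 * g1 + g2) * s2xi,
                  g1 * s2xi, s2e1, b1 * s2e1 + g1 * g2 * s2xi,
                  (b1 * g1 + g2) * s2xi, b1 * s2e1 + g1 * g2 * s2xi, s2e2),
                3, 3, dimnames = list(c("xi", "eta1", "eta2"),
                                      c("xi", "eta1", "eta2")))
  phi
}

loading_matrix <- function(bp) {
  p <- block_sizes(bp)
  L <- matrix(0, sum(p), 3)
  L[seq_len(p[1]), 1] <- bp$lambda_x
  L[p[1] + seq_len(p[2]), 2] <- bp$lambda_y1
  L[p[1] + p[2] + seq_len(p[3]), 3] <- bp$lambda_y2
  L
}

indicator_names <- function(p = c(3L, 3L, 3L)) {
  c(paste0("x", seq_len(p[1])), paste0("y", seq_len(p[2])),
    paste0("y", p[2] + seq_len(p[3])))
}

#' Model-implied covariance matrix
#'
#' Builds the reduced-form implied covariance
#' \eqn{\Sigma(\theta) = \Lambda \Phi \Lambda' + \Psi}, where \eqn{\Phi} is
#' the latent covariance matrix from [latent_cov()] and \eqn{\Psi} the
#' diagonal measurement-error matrix.
#'
#' @param bp a [base_params()] object.
#' @return A list of class `"implied_moments"` with elements `sigma`
#'   (p x p positive definite), `sigma2_eta1`, `sigma2_eta2`, `cov_latent`.
#' @export
implied_covariance <- function(bp) {
  validate_base_params(bp)
  phi <- latent_cov(bp)
  L <- loading_matrix(bp)
  psi <- c(bp$psi_x, bp$psi_y1, bp$psi_y2)
  sigma <- L %*% phi %*% t(L) + diag(psi)
  nm <- indicator_names(block_sizes(bp))
  dimnames(sigma) <- list(nm, nm)
  ev <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10)
    stop("implied covariance not positive definite (min eigenvalue ",
         format(ev), "); check variance parameters")
  structure(list(sigma = sigma,
                 sigma2_eta1 = phi["eta1", "eta1"],
                 sigma2_eta2 = phi["eta2", "eta2"],
                 cov_latent = phi),
            class = "implied_moments")
}

#' Generate random parameter conditions
#'
#' Draws each of the 21 free parameters independently from Uniform(0.2, 1.2)
#' (a uniform draw on the unit interval shifted by 0.2 so that no parameter
#' is close to zero) and keeps the identification values fixed
#' (anchor loadings and \eqn{\sigma^2_\xi} at 1.0). Each row of draws, in the
#' order documented in [as_theta()], defines one population condition.
#'
#' @param n_conditions number of conditions to generate (>= 1).
#' @param seed integer seed; the same seed reproduces the same conditions.
#' @return A list of [base_params()] objects of class `"condition_set"`, with
#'   the seed stored in `attr(, "seed")`. `as.matrix()` returns the
#'   n x 21 matrix of free parameters.
#' @export
generate_conditions <- function(n_conditions, seed) {
  if (!is.numeric(n_conditions) || length(n_conditions) != 1 ||
      n_conditions < 1 || n_conditions != round(n_conditions))
    stop("n_conditions must be a positive integer")
  n_conditions <- as.integer(n_conditions)
  q <- 21L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  m <- matrix(stats::runif(n_conditions * q), n_conditions, q, byrow = TRUE) + 0.2
  conds <- lapply(seq_len(n_conditions), function(i) params_from_theta(m[i, ]))
  structure(conds, class = "condition_set", seed = as.integer(seed))
}

#' @export
as.matrix.condition_set <- function(x, ...) {
  m <- do.call(rbind, lapply(x, as_theta))
  rownames(m) <- NULL
  m
}

#' @export
print.condition_set <- function(x, ...) {
  cat("condition_set:", length(x), "mediation-model conditions")
  if (!is.null(attr(x, "seed"))) cat(" (seed ", attr(x, "seed"), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Read and write condition files
#'
#' Condition files are numeric CSV tables with 21 columns, one condition per
#' row, in the free-parameter order of [as_theta()]. The canonical form is
#' headerless; a headered variant (matching the [as_theta()] names) is also
#' accepted on read.
#'
#' @param path file path.
#' @param conditions a `"condition_set"` or list of [base_params()].
#' @return `load_conditions()` returns a `"condition_set"`;
#'   `write_conditions()` returns `path` invisibly.
#' @export
load_conditions <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- any(is.na(suppressWarnings(
    as.numeric(strsplit(first, ",", fixed = TRUE)[[1]]))))
  tab <- utils::read.csv(path, header = has_header)
  if (ncol(tab) != 21L)
    stop("condition file must have 21 columns; found ", ncol(tab))
  if (!all(vapply(tab, is.numeric, logical(1))))
    stop("condition file contains non-numeric entries")
  conds <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    conds[[i]] <- tryCatch(params_from_theta(as.numeric(tab[i, ])),
                           error = function(e)
                             stop("invalid condition in row ", i, ": ",
                                  conditionMessage(e), call. = FALSE))
  }
  structure(conds, class = "condition_set")
}

#' @rdname load_conditions
#' @export
write_conditions <- function(conditions, path) {
  m <- as.matrix.condition_set(conditions)
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Simulate indicator data from a condition
#'
#' Draws `n` observations from the multivariate normal distribution
#' \eqn{N(0, \Sigma(\theta))} via the Cholesky factor of the implied
#' covariance matrix.
#'
#' @param bp a [base_params()] object.
#' @param n number of observations.
#' @return an `n x p` numeric matrix with indicator column names.
#' @export
simulate_indicators <- function(bp, n) {
  sigma <- implied_covariance(bp)$sigma
  R <- chol(sigma)
  x <- matrix(stats::rnorm(n * ncol(sigma)), n, ncol(sigma)) %*% R
  colnames(x) <- colnames(sigma)
  x
}
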
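# Batch SNR computation across parameter conditions: population
# (asymptotic) SNRs from closed forms, and empirical SNRs via simulation.

medsnr_methods <- c("SEM", "paBFS_w", "paBFS_what", "paEWC")

new_condition_batch <- function(df, conditions, mode, seed = NULL,
                                exclusions = NULL, settings = list()) {
  structure(df, class = c("condition_batch", "data.frame"),
            conditions = conditions, mode = mode, seed = seed,
            exclusions = exclusions %||%
              data.frame(condition = integer(), reason = character()),
            settings = settings)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Population SNRs for a batch of conditions
#'
#' For every condition, computes the population SNR of the three structural
#' coefficients and of the indirect effect under the four methods:
#' `"SEM"` (normal-theory ML, inverse expected information and delta
#' method), `"paBFS_w"` (path analysis with Bartlett-factor scores,
#' population weights), `"paBFS_what"` (Bartlett-factor scores with
#' estimated weights, delta method over the sample covariance matrix), and
#' `"paEWC"` (equally weighted composites). No data are simulated; all
#' quantities are functions of the population parameters.
#'
#' The `tau_a`, `tau_c`, `tau_b`, `tau_ab` columns refer to the
#' path-analysis coefficients \eqn{a, c, b, ab}; for `"SEM"` they hold the
#' SNRs of the corresponding structural parameters
#' \eqn{\gamma_1, \gamma_2, \beta_1, \gamma_1\beta_1}.
#'
#' @param conditions a `"condition_set"` or list of [base_params()].
#' @param methods subset of `c("SEM", "paBFS_w", "paBFS_what", "paEWC")`.
#' @return a `"condition_batch"` data frame with columns `condition`,
#'   `method`, `tau_a`, `tau_c`, `tau_b`, `tau_ab`; conditions that fail
#'   are excluded and logged in `attr(, "exclusions")`.
#' @export
population_batch <- function(conditions, methods = medsnr_methods) {
  methods <- match.arg(methods, medsnr_methods, several.ok = TRUE)
  rows <- list()
  excl <- list()
  for (i in seq_along(conditions)) {
    bp <- conditions[[i]]
    res <- tryCatch({
      out <- list()
      if ("SEM" %in% methods) {
        s <- population_snr_sem(bp)
        out$SEM <- c(s$tau_gamma1, s$tau_gamma2, s$tau_beta1, s$tau_indirect)
      }
      if ("paBFS_w" %in% methods) {
        pw <- pawc_population(bp, bartlett_weights(bp))
        out$paBFS_w <- c(pw$tau_a, pw$tau_c, pw$tau_b, pw$tau_ab)
      }
      if ("paBFS_what" %in% methods) {
        wh <- snr_estimated_weights(bp)
        out$paBFS_what <- unname(wh$tau[c("a", "c", "b", "ab")])
      }
      if ("paEWC" %in% methods) {
        ew <- pawc_population(bp, equal_weights(bp))
        out$paEWC <- c(ew$tau_a, ew$tau_c, ew$tau_b, ew$tau_ab)
      }
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excl[[length(excl) + 1L]] <-
        data.frame(condition = i, reason = conditionMessage(res))
      next
    }
    for (m in names(res)) {
      rows[[length(rows) + 1L]] <- data.frame(
        condition = i, method = m,
        tau_a = res[[m]][1], tau_c = res[[m]][2],
        tau_b = res[[m]][3], tau_ab = res[[m]][4])
    }
  }
  if (!length(rows))
    stop("all conditions failed; first reason: ", excl[[1]]$reason)
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  new_condition_batch(df, conditions, mode = "population",
                      seed = attr(conditions, "seed"),
                      exclusions = if (length(excl)) do.call(rbind, excl))
}

#' @export
print.condition_batch <- function(x, ...) {
  cat("condition_batch [", attr(x, "mode"), " mode]: ",
      length(unique(x$condition)), " conditions x ",
      length(unique(x$method)), " methods\n", sep = "")
  ex <- attr(x, "exclusions")
  if (!is.null(ex) && nrow(ex))
    cat("  excluded conditions:", nrow(ex), "\n")
  NextMethod()
}

#' Summary statistics of a condition batch
#'
#' Six summary statistics (minimum, maximum, median, mean, SD and
#' coefficient of variation CV = SD/mean) of each SNR column, per method.
#'
#' @param object a `"condition_batch"`.
#' @param ... unused.
#' @return data frame with one row per method x parameter.
#' @export
summary.condition_batch <- function(object, ...) {
  params <- c("tau_a", "tau_c", "tau_b", "tau_ab")
  out <- list()
  for (m in unique(object$method)) {
    sub <- object[object$method == m, , drop = FALSE]
    for (pp in params) {
      v <- sub[[pp]]
      out[[length(out) + 1L]] <- data.frame(
        method = m, parameter = sub("tau_", "", pp),
        min = min(v), max = max(v), median = stats::median(v),
        mean = mean(v), sd = stats::sd(v),
        cv = stats::sd(v) / mean(v))
    }
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Pairwise comparison counts between methods
#'
#' For every ordered pair of methods in the batch and each of the four
#' parameters, counts the conditions in which the first method's SNR is
#' strictly greater than the second's.
#'
#' @param batch a `"condition_batch"`.
#' @return data frame with columns `greater`, `smaller`, `a`, `c`, `b`,
#'   `ab`, and `n` (number of conditions compared).
#' @export
pairwise_counts <- function(batch) {
  methods <- unique(batch$method)
  params <- c("tau_a", "tau_c", "tau_b", "tau_ab")
  wide <- lapply(methods, function(m)
    batch[batch$method == m, c("condition", params)])
  names(wide) <- methods
  out <- list()
  for (m1 in methods) for (m2 in methods) {
    if (m1 == m2) next
    merged <- merge(wide[[m1]], wide[[m2]], by = "condition",
                    suffixes = c(".1", ".2"))
    counts <- vapply(params, function(pp)
      sum(merged[[paste0(pp, ".1")]] > merged[[paste0(pp, ".2")]]),
      integer(1))
    out[[length(out) + 1L]] <- data.frame(
      greater = m1, smaller = m2,
      a = counts[1], c = counts[2], b = counts[3], ab = counts[4],
      n = nrow(merged))
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Empirical SNRs via Monte Carlo simulation
#'
#' For each condition, draws `n_reps` independent samples of size `N` from
#' the implied normal population, obtains per-replication estimates of the
#' structural coefficients and the indirect effect under the requested
#' methods, and forms the empirical SNR
#' \eqn{\hat\tau = \bar\theta / (\sqrt{N}\, SD(\hat\theta))}
#' with the replication mean and standard deviation.
#'
#' Per replication: the SEM is fit by normal-theory ML (started at the true
#' parameters); Bartlett weights for `"paBFS_what"` are recomputed from the
#' fitted loadings and error variances; `"paBFS_w"` and `"paEWC"` score the
#' data with population weights. A replication whose SEM fit fails to
#' converge (after one retry from a perturbed start) or hits a variance
#' boundary is excluded for the fit-dependent methods and logged; a
#' condition is dropped entirely when more than 10% of its replications
#' fail.
#'
#' Per-condition RNG streams are derived from `seed`, so results do not
#' depend on the order in which conditions are processed.
#'
#' @param conditions a `"condition_set"` or list of [base_params()].
#' @param N sample size per replication.
#' @param n_reps replications per condition (>= 2).
#' @param seed integer master seed.
#' @param methods subset of the four method tags.
#' @return a `"condition_batch"` with `mode = "empirical"`; the exclusion
#'   log in `attr(, "exclusions")` reports failed replication counts.
#' @export
empirical_snr <- function(conditions, N = 200, n_reps = 1000, seed,
                          methods = medsnr_methods) {
  methods <- match.arg(methods, medsnr_methods, several.ok = TRUE)
  if (n_reps < 2) stop("n_reps must be at least 2 to form an SD")
  q <- 21L
  if (("SEM" %in% methods || "paBFS_what" %in% methods) && N <= q)
    stop("N must exceed the number of free parameters (", q, ") for SEM fits")
  n_cond <- length(conditions)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  cond_seeds <- sample.int(.Machine$integer.max - 1L, n_cond)
  needs_fit <- any(c("SEM", "paBFS_what") %in% methods)

  rows <- list()
  excl <- list()
  for (i in seq_len(n_cond)) {
    bp <- conditions[[i]]
    sigma <- implied_covariance(bp)$sigma
    R <- chol(sigma)
    np <- ncol(sigma)
    specs <- list()
    if ("paBFS_w" %in% methods) specs$paBFS_w <- weight_matrix(bartlett_weights(bp))
    if ("paEWC" %in% methods) specs$paEWC <- weight_matrix(equal_weights(bp))
    est <- lapply(methods, function(m) matrix(NA_real_, n_reps, 4))
    names(est) <- methods
    n_fail <- 0L
    set.seed(cond_seeds[i])
    for (r in seq_len(n_reps)) {
      X <- matrix(stats::rnorm(N * np), N, np) %*% R
      Xc <- sweep(X, 2, colMeans(X))
      fit <- NULL
      if (needs_fit) {
        S <- crossprod(Xc) / N
        fit <- nml_fit(S, N, start = bp, se = FALSE)
        if (!fit$converged || fit$heywood) {
          jitter <- as_theta(bp) * stats::runif(q, 0.8, 1.2)
          fit <- nml_fit(S, N, start = jitter, se = FALSE)
        }
        if (!fit$converged || fit$heywood) {
          n_fail <- n_fail + 1L
          fit <- NULL
        }
      }
      if (!is.null(fit)) {
        if ("SEM" %in% methods) {
          idx <- sem_indices()
          th <- fit$theta_hat
          est$SEM[r, ] <- c(th[idx$gamma1], th[idx$gamma2], th[idx$beta1],
                            th[idx$gamma1] * th[idx$beta1])
        }
        if ("paBFS_what" %in% methods) {
          wsp <- tryCatch(bartlett_weights(fit), error = function(e) NULL)
          if (!is.null(wsp)) {
            ls <- ls_fit_paths(Xc %*% weight_matrix(wsp))
            est$paBFS_what[r, ] <- c(ls$a, ls$c, ls$b, ls$ab)
          }
        }
      }
      for (m in names(specs)) {
        ls <- ls_fit_paths(Xc %*% specs[[m]])
        est[[m]][r, ] <- c(ls$a, ls$c, ls$b, ls$ab)
      }
    }
    if (n_fail > 0.10 * n_reps) {
      excl[[length(excl) + 1L]] <- data.frame(
        condition = i,
        reason = sprintf("dropped: %d of %d replications failed",
                         n_fail, n_reps))
      next
    }
    if (n_fail > 0)
      excl[[length(excl) + 1L]] <- data.frame(
        condition = i,
        reason = sprintf("%d of %d replications excluded", n_fail, n_reps))
    for (m in methods) {
      e <- est[[m]][stats::complete.cases(est[[m]]), , drop = FALSE]
      tau <- colMeans(e) / (sqrt(N) * apply(e, 2, stats::sd))
      rows[[length(rows) + 1L]] <- data.frame(
        condition = i, method = m,
        tau_a = tau[1], tau_c = tau[2], tau_b = tau[3], tau_ab = tau[4])
    }
  }
  if (!length(rows))
    stop("all conditions were dropped; first reason: ", excl[[1]]$reason)
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  new_condition_batch(df, conditions, mode = "empirical",
                      seed = as.integer(seed),
                      exclusions = if (length(excl)) do.call(rbind, excl),
                      settings = list(N = N, n_reps = n_reps))
}

#' Covariates of the SNR difference and their correlations
#'
#' Assembles, per condition, the 37 candidate covariates of the SNR
#' difference \eqn{\tau_d = \tau_{ab} - \tau_{\gamma_1\beta_1}}: the 21 base
#' parameters, the 3 composite reliabilities of the scheme, the 9
#' individual-indicator reliabilities, and the four component SNRs
#' \eqn{\tau_{\gamma_1}, \tau_{\beta_1}, \tau_a, \tau_b} (the latter two
#' evaluated under the scheme's weights). Covariates are population values;
#' \eqn{\tau_d} is taken from the batch (empirical or population mode).
#'
#' @param batch a `"condition_batch"` containing the `"SEM"` rows and the
#'   rows of `scheme`.
#' @param scheme one of `"paBFS_w"`, `"paBFS_what"`, `"paEWC"`.
#' @return list with `covariates` (data frame: `condition`, 37 covariate
#'   columns, `tau_d`) and `correlations` (data frame: `covariate`, `r`,
#'   `r2`, `salient` flag for r^2 > 0.05; constant covariates get `NA`).
#' @export
covariates_and_correlations <- function(batch,
                                        scheme = c("paBFS_w", "paBFS_what",
                                                   "paEWC")) {
  scheme <- match.arg(scheme)
  conditions <- attr(batch, "conditions")
  if (is.null(conditions)) stop("batch does not carry its conditions")
  sem_rows <- batch[batch$method == "SEM", c("condition", "tau_ab")]
  sch_rows <- batch[batch$method == scheme, c("condition", "tau_ab")]
  merged <- merge(sch_rows, sem_rows, by = "condition",
                  suffixes = c(".pawc", ".sem"))
  rows <- list()
  for (i in merged$condition) {
    bp <- conditions[[i]]
    theta <- as_theta(bp)
    mom <- implied_covariance(bp)
    rel1 <- function(lambda, psi, s2f) lambda^2 * s2f / (lambda^2 * s2f + psi)
    rho_ind <- c(rel1(bp$lambda_x, bp$psi_x, bp$sigma2_xi),
                 rel1(bp$lambda_y1, bp$psi_y1, mom$sigma2_eta1),
                 rel1(bp$lambda_y2, bp$psi_y2, mom$sigma2_eta2))
    names(rho_ind) <- paste0("rho_", indicator_names(block_sizes(bp)))
    sem <- population_snr_sem(bp)
    if (scheme == "paBFS_what") {
      wh <- snr_estimated_weights(bp)
      spec <- bartlett_weights(bp)
      tau_a <- unname(wh$tau["a"]); tau_b <- unname(wh$tau["b"])
    } else {
      spec <- if (scheme == "paEWC") equal_weights(bp) else bartlett_weights(bp)
      pw <- pawc_population(bp, spec)
      tau_a <- pw$tau_a; tau_b <- pw$tau_b
    }
    rows[[length(rows) + 1L]] <- data.frame(
      condition = i, t(theta),
      rho_xi_hat = spec$rho_xi, rho_eta1_hat = spec$rho_eta1,
      rho_eta2_hat = spec$rho_eta2, t(rho_ind),
      tau_gamma1 = sem$tau_gamma1, tau_beta1 = sem$tau_beta1,
      tau_a = tau_a, tau_b = tau_b)
  }
  cov_df <- do.call(rbind, rows)
  cov_df$tau_d <- merged$tau_ab.pawc - merged$tau_ab.sem
  covariates <- setdiff(names(cov_df), c("condition", "tau_d"))
  cors <- vapply(covariates, function(v) {
    x <- cov_df[[v]]
    if (stats::sd(x) < 1e-12) return(NA_real_)
    stats::cor(x, cov_df$tau_d)
  }, numeric(1))
  correlations <- data.frame(covariate = covariates, r = unname(cors),
                             r2 = unname(cors)^2,
                             salient = !is.na(cors) & cors^2 > 0.05)
  correlations <- correlations[order(-abs(correlations$r)), ]
  rownames(correlations) <- NULL
  list(covariates = cov_df, correlations = correlations)
}
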
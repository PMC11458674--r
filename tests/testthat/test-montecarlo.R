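test_that("population batch rows agree with the per-condition functions", {
  conds <- generate_conditions(3, seed = 112)
  batch <- population_batch(conds)
  expect_s3_class(batch, "condition_batch")
  expect_equal(nrow(batch), 12L)
  bp <- conds[[2]]
  sem <- population_snr_sem(bp)
  row <- batch[batch$condition == 2 & batch$method == "SEM", ]
  expect_equal(row$tau_ab, sem$tau_indirect)
  expect_equal(row$tau_a, sem$tau_gamma1)
  pw <- pawc_population(bp, equal_weights(bp))
  row <- batch[batch$condition == 2 & batch$method == "paEWC", ]
  expect_equal(row$tau_ab, pw$tau_ab)
  wh <- snr_estimated_weights(bp)
  row <- batch[batch$condition == 2 & batch$method == "paBFS_what", ]
  expect_equal(row$tau_ab, wh$tau_ab_hat)
})

test_that("near-error-free composites collapse the conditional PAWC methods", {
  # as psi -> 0 the reliabilities go to 1: Bartlett and equal weights become
  # interchangeable and the conditional-on-weights SNRs coincide; the SNR of
  # the composite methods stays above SEM, whose estimates carry the cost of
  # the measurement model even with nearly perfect indicators
  bp <- fixture_params()
  bp$psi_x[] <- bp$psi_y1[] <- bp$psi_y2[] <- 1e-3
  batch <- population_batch(list(bp))
  expect_equal(nrow(batch), 4L)
  w <- batch[batch$method == "paBFS_w", ]
  e <- batch[batch$method == "paEWC", ]
  expect_equal(w$tau_ab, e$tau_ab, tolerance = 1e-4)
  expect_equal(w$tau_a, e$tau_a, tolerance = 1e-4)
  # conditional-on-weights tau_ab approaches the error-free path analysis
  pw1 <- pawc_population(bp, composite_spec(rep(1, 3), rep(1, 3), rep(1, 3),
                                            rho = c(1, 1, 1)))
  expect_equal(w$tau_ab, pw1$tau_ab, tolerance = 1e-3)
  expect_lt(batch$tau_ab[batch$method == "SEM"], w$tau_ab)
})

test_that("batch summaries compute the six statistics correctly", {
  conds <- generate_conditions(2, seed = 221)
  batch <- population_batch(conds, methods = "paEWC")
  s <- summary(batch)
  expect_equal(nrow(s), 4L)
  v <- batch$tau_ab
  row <- s[s$parameter == "ab", ]
  expect_equal(row$min, min(v)); expect_equal(row$max, max(v))
  expect_equal(row$median, median(v)); expect_equal(row$mean, mean(v))
  expect_equal(row$sd, sd(v)); expect_equal(row$cv, sd(v) / mean(v))
  # constant batch: both conditions identical
  cb <- population_batch(list(conds[[1]], conds[[1]]), methods = "SEM")
  sc <- summary(cb)
  expect_true(all(sc$sd == 0) && all(sc$cv == 0))
  expect_true(all(sc$min == sc$max & sc$median == sc$mean))
})

test_that("pairwise counts are consistent and bounded", {
  conds <- generate_conditions(20, seed = 331)
  batch <- population_batch(conds)
  pc <- pairwise_counts(batch)
  expect_equal(nrow(pc), 12L)   # ordered pairs of 4 methods
  for (i in seq_len(nrow(pc))) {
    rev <- pc[pc$greater == pc$smaller[i] & pc$smaller == pc$greater[i], ]
    # strict comparisons in both directions cannot exceed n
    expect_lte(pc$ab[i] + rev$ab, pc$n[i])
    expect_lte(pc$a[i] + rev$a, pc$n[i])
  }
})

test_that("empirical SNR machinery is seeded, validated, and finite", {
  conds <- generate_conditions(3, seed = 441)
  expect_error(empirical_snr(conds, N = 200, n_reps = 1, seed = 1), "at least 2")
  expect_error(empirical_snr(conds, N = 20, n_reps = 10, seed = 1), "exceed")
  b1 <- empirical_snr(conds, N = 200, n_reps = 25, seed = 5)
  b2 <- empirical_snr(conds, N = 200, n_reps = 25, seed = 5)
  expect_equal(as.data.frame(b1), as.data.frame(b2))
  expect_true(all(is.finite(b1$tau_ab)))
  expect_equal(sort(unique(b1$method)), sort(medsnr_methods))
  # population-weight methods do not need the SEM fit
  b3 <- empirical_snr(conds, N = 200, n_reps = 10, seed = 5,
                      methods = c("paBFS_w", "paEWC"))
  expect_equal(sort(unique(b3$method)), c("paBFS_w", "paEWC"))
})

test_that("empirical SNRs track the population SNRs at moderate N", {
  conds <- generate_conditions(4, seed = 551)
  emp <- empirical_snr(conds, N = 300, n_reps = 120, seed = 552)
  pop <- population_batch(conds)
  m <- merge(as.data.frame(emp), as.data.frame(pop),
             by = c("condition", "method"), suffixes = c(".emp", ".pop"))
  # agreement is loose at 120 reps; this is a sanity check, not calibration
  expect_gt(cor(m$tau_ab.emp, m$tau_ab.pop), 0.9)
})

test_that("covariate table has the 37 candidates with the documented signs", {
  conds <- generate_conditions(150, seed = 661)
  batch <- population_batch(conds)
  cc <- covariates_and_correlations(batch, scheme = "paBFS_w")
  expect_equal(ncol(cc$covariates), 39L)   # condition + 37 covariates + tau_d
  expect_equal(nrow(cc$correlations), 37L)
  r <- function(nm) cc$correlations$r[cc$correlations$covariate == nm]
  # strong positive association of the predictor-mediator path with tau_d,
  # negative association of the mediator's residual variance
  expect_gt(r("gamma1"), 0.5)
  expect_lt(r("sigma2_zeta1"), -0.2)
  expect_gt(r("tau_a"), 0.5)
  expect_true(all(cc$correlations$salient ==
                    (!is.na(cc$correlations$r) & cc$correlations$r2 > 0.05)))
})

test_that("constant covariates are reported as missing", {
  conds <- generate_conditions(30, seed = 771)
  for (i in seq_along(conds)) conds[[i]]$gamma2 <- 0.5
  batch <- population_batch(conds, methods = c("SEM", "paEWC"))
  cc <- covariates_and_correlations(batch, scheme = "paEWC")
  expect_true(is.na(cc$correlations$r[cc$correlations$covariate == "gamma2"]))
})
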
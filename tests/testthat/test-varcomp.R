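# REML variance-component fit: oracle equivalence, invariances, CIs

test_that("constant data collapse to the mean with zero variance components", {
  d <- expand.grid(patient_id = c("A", "B", "C"), fraction = 1:2,
                   frame = 1:4)
  d$error_mm <- 0.7
  fit <- varcomp(error_mm ~ patient_id/fraction, d)
  expect_equal(fit$M, 0.7)
  expect_equal(unname(fit$sigma), c(0, 0, 0))
  expect_true(all(fit$ci[c("sigma_pt", "sigma_fr", "sigma_intra"), ] == 0))
})

test_that("REML matches the expected-mean-squares ANOVA oracle on balanced designs", {
  designs <- list(c(4, 3, 5), c(5, 4, 6), c(3, 4, 2))
  interior_seen <- 0L
  for (i in seq_along(designs)) {
    dd <- designs[[i]]
    d <- simulate_errors(simulation_spec(
      n_patients = dd[1], n_fractions = dd[2], n_fields = 1,
      frames_per_field = dd[3], mean_M = 0.5,
      sigma_pt = 1.2, sigma_fr = 1.0, sigma_intra = 0.9,
      seed = 400 + i))
    oracle <- ems_nested_anova(d$error_mm, d$patient_id, d$fraction)
    if (!oracle$interior) next
    interior_seen <- interior_seen + 1L
    fit <- varcomp(error_mm ~ patient_id/fraction, d, ci_method = "none")
    expect_equal(fit$sigma[["sigma_pt"]], sqrt(oracle$va), tolerance = 1e-6)
    expect_equal(fit$sigma[["sigma_fr"]], sqrt(oracle$vb), tolerance = 1e-6)
    expect_equal(fit$sigma[["sigma_intra"]], sqrt(oracle$ve),
                 tolerance = 1e-6)
    expect_equal(fit$M, oracle$mean, tolerance = 1e-8)
  }
  expect_gte(interior_seen, 2L)
})

test_that("REML agrees with lme4 on an unbalanced design", {
  skip_if_not_installed("lme4")
  d <- simulate_errors(simulation_spec(
    n_patients = 7, n_fractions = 5, breath_hold_s = c(4, 1.5),
    frame_rate_hz = 2, seed = 17))
  fit <- varcomp(error_mm ~ patient_id/fraction, d, ci_method = "none")
  lf <- lme4::lmer(error_mm ~ 1 + (1 | patient_id) +
                     (1 | patient_id:fraction), d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  ref <- setNames(vc$sdcor, vc$grp)
  expect_equal(fit$M, unname(lme4::fixef(lf)), tolerance = 1e-6)
  # lme4's optimizer stops at ~1e-4 relative precision on the SDs, so match
  # estimates loosely and require our restricted likelihood to be at least
  # as good as lme4's at its own optimum
  expect_equal(fit$sigma[["sigma_pt"]], ref[["patient_id"]],
               tolerance = 1e-4)
  expect_equal(fit$sigma[["sigma_fr"]], ref[["patient_id:fraction"]],
               tolerance = 1e-4)
  expect_equal(fit$sigma[["sigma_intra"]], ref[["Residual"]],
               tolerance = 1e-4)
  expect_equal(fit$logREML, as.numeric(logLik(lf)), tolerance = 1e-8)
  expect_gte(fit$logREML, as.numeric(logLik(lf)) - 1e-7)
})

test_that("estimates are invariant to relabeling patients and fractions", {
  d <- simulate_errors(simulation_spec(n_patients = 5, n_fractions = 3,
                                       frames_per_field = 6, seed = 23))
  fit1 <- varcomp(error_mm ~ patient_id/fraction, d, ci_method = "none")
  d2 <- d
  # permute patient labels and reverse fraction labels within patients
  perm <- setNames(sample(unique(d$patient_id)), unique(d$patient_id))
  d2$patient_id <- unname(perm[d$patient_id])
  d2$fraction <- max(d$fraction) + 1 - d$fraction
  d2 <- d2[sample(nrow(d2)), ]
  fit2 <- varcomp(error_mm ~ patient_id/fraction, d2, ci_method = "none")
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-7)
})

test_that("shift and scale equivariance hold", {
  d <- simulate_errors(simulation_spec(n_patients = 5, n_fractions = 3,
                                       frames_per_field = 6, seed = 29))
  fit <- varcomp(error_mm ~ patient_id/fraction, d, ci_method = "none")
  d_shift <- transform(d, error_mm = error_mm + 2.5)
  fit_shift <- varcomp(error_mm ~ patient_id/fraction, d_shift,
                       ci_method = "none")
  expect_equal(fit_shift$M, fit$M + 2.5, tolerance = 1e-6)
  expect_equal(fit_shift$sigma, fit$sigma, tolerance = 1e-5)

  d_scale <- transform(d, error_mm = error_mm * -3)
  fit_scale <- varcomp(error_mm ~ patient_id/fraction, d_scale,
                       ci_method = "none")
  expect_equal(fit_scale$M, -3 * fit$M, tolerance = 1e-6)
  expect_equal(unname(fit_scale$sigma), unname(3 * fit$sigma),
               tolerance = 1e-5)
})

test_that("degenerate designs raise identifiability errors", {
  one_pat <- data.frame(patient_id = "A", fraction = rep(1:3, each = 4),
                        error_mm = rnorm(12))
  expect_error(varcomp(error_mm ~ patient_id/fraction, one_pat),
               "single patient", class = "dibh_validation_error")

  singletons <- expand.grid(patient_id = c("A", "B", "C"), fraction = 1:4)
  singletons$error_mm <- rnorm(12)
  expect_error(varcomp(error_mm ~ patient_id/fraction, singletons),
               "single", class = "dibh_validation_error")

  one_frac <- data.frame(patient_id = rep(c("A", "B"), each = 6),
                         fraction = 1, error_mm = rnorm(12))
  expect_error(varcomp(error_mm ~ patient_id/fraction, one_frac),
               "fraction", class = "dibh_validation_error")

  expect_error(varcomp(error_mm ~ patient_id/fraction,
                       data.frame(patient_id = "A", fraction = 1,
                                  error_mm = NaN)),
               "error_mm", class = "dibh_validation_error")
})

test_that("boundary variance components are detected and pinned at zero", {
  set.seed(61)
  d <- expand.grid(patient_id = sprintf("P%d", 1:6), fraction = 1:4,
                   frame = 1:5)
  d$error_mm <- rnorm(nrow(d))          # no patient or fraction effects
  fit <- varcomp(error_mm ~ patient_id/fraction, d)
  # with no true patient/fraction effects the estimates sit near zero
  # (sampling noise on the variance scale allows up to a few tenths)
  expect_true(fit$sigma[["sigma_pt"]] < 0.4)
  expect_true(fit$sigma[["sigma_fr"]] < 0.4)
  sd_rows <- c("sigma_pt", "sigma_fr", "sigma_intra")
  expect_gte(min(fit$ci[sd_rows, ]), 0)  # SD intervals bounded below by 0
  if (any(fit$boundary)) {
    flags <- attr(fit$ci, "flags")
    bset <- c(va = "sigma_pt", vb = "sigma_fr")[names(which(fit$boundary[1:2]))]
    expect_true(all(flags[bset] == "boundary-one-sided"))
  }
})

test_that("confidence intervals behave across levels and methods", {
  d <- simulate_errors(simulation_spec(n_patients = 8, n_fractions = 4,
                                       frames_per_field = 10, seed = 37))
  fit <- varcomp(error_mm ~ patient_id/fraction, d)
  # point estimate inside its interval
  expect_true(all(fit$ci[, 1] <= c(fit$M, fit$sigma) + 1e-9))
  expect_true(all(c(fit$M, fit$sigma) <= fit$ci[, 2] + 1e-9))
  # level 0 collapses to the estimate
  ci0 <- confint(fit, level = 0)
  expect_equal(unname(ci0[, 1]), unname(c(fit$M, fit$sigma)))
  expect_equal(unname(ci0[, 2]), unname(c(fit$M, fit$sigma)))
  # wider level, wider interval
  ci99 <- confint(fit, level = 0.99)
  expect_true(all(ci99[, 2] - ci99[, 1] >= fit$ci[, 2] - fit$ci[, 1] - 1e-9))
  # parametric bootstrap brackets the point estimates too
  cib <- confint(fit, level = 0.9, method = "bootstrap", nsim = 30, seed = 1)
  expect_true(all(cib[, 1] <= c(fit$M, fit$sigma)
                  & c(fit$M, fit$sigma) <= cib[, 2]))
})

test_that("interval widths order as patient > fraction > residual at study scale", {
  d <- simulate_errors(simulation_spec(frames_per_field = 15, seed = 53))
  fit <- varcomp(error_mm ~ patient_id/fraction, d)
  w <- fit$ci[, 2] - fit$ci[, 1]
  expect_gt(w[["sigma_pt"]], w[["sigma_fr"]])
  expect_gt(w[["sigma_fr"]], w[["sigma_intra"]])
})

test_that("overall_mean_test excludes zero only when the CI does", {
  d <- simulate_errors(simulation_spec(n_patients = 6, n_fractions = 4,
                                       frames_per_field = 10, mean_M = 25,
                                       seed = 3))
  fit_hi <- varcomp(error_mm ~ patient_id/fraction, d)
  expect_true(overall_mean_test(fit_hi))

  d0 <- transform(d, error_mm = error_mm - mean(error_mm))
  fit0 <- varcomp(error_mm ~ patient_id/fraction, d0)
  expect_false(overall_mean_test(fit0))

  # boundary convention: an interval touching 0 does not exclude it
  fit_edge <- fit_hi
  fit_edge$ci["M", ] <- c(-0.2, 0)
  expect_false(overall_mean_test(fit_edge))
  fit_edge$ci["M", ] <- c(0.1, 0.5)
  expect_true(overall_mean_test(fit_edge))
})

test_that("fit methods are mutually consistent", {
  d <- simulate_errors(simulation_spec(n_patients = 5, n_fractions = 3,
                                       frames_per_field = 8, seed = 41))
  fit <- varcomp(error_mm ~ patient_id/fraction, d, ci_method = "none")
  expect_equal(fitted(fit) + residuals(fit), d$error_mm, tolerance = 1e-10)
  expect_equal(mean(residuals(fit, type = "marginal")) + fit$M,
               mean(d$error_mm), tolerance = 1e-10)
  expect_equal(predict(fit), fitted(fit))
  nd <- data.frame(patient_id = c(d$patient_id[1], "NEW"),
                   fraction = c(d$fraction[1], 1))
  pr <- predict(fit, nd)
  expect_equal(pr[2], fit$M)            # unseen patient -> population mean
  expect_equal(nobs(fit), nrow(d))
  expect_equal(attr(logLik(fit), "df"), 4L)
  sims <- simulate(fit, nsim = 3, seed = 2)
  expect_equal(dim(sims), c(nrow(d), 3L))
  re <- random_effects(fit)
  expect_length(re$patient, 5L)
  # BLUP shrinkage: patient effects shrink toward zero relative to raw means
  raw <- tapply(d$error_mm, d$patient_id, mean) - mean(d$error_mm)
  expect_true(all(abs(re$patient) <= abs(raw[names(re$patient)]) + 1e-8))
})
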
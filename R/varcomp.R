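# User-facing fit: variance component analysis of breath-hold positional
# errors by REML under the nested random-effect model.

#' Fit the nested variance-component model by REML
#'
#' Estimates the overall mean error M and the inter-patient, inter-fraction
#' and intra-fraction standard deviations (Sigma_pt, sigma_fr, sigma_intra)
#' of signed chest-wall positional errors by restricted maximum likelihood
#' under the nested random-effect model
#' `error = M + a_patient + b_patient:fraction + e`, with all three effects
#' independent zero-mean Gaussians. Fraction labels are interpreted within
#' patient (fully nested); field labels are not a model level. Unbalanced
#' designs are supported, and the likelihood is evaluated from per-fraction
#' sufficient statistics so hundreds of thousands of frames fit in seconds.
#'
#' Variances are optimized on the log scale; a component collapsing toward
#' zero is refit pinned at the boundary and flagged. Confidence intervals
#' are profile restricted-likelihood intervals for the three SDs (bounded
#' below by 0; one-sided with a flag at a boundary estimate) and a Wald
#' interval for M. A parametric bootstrap is available via
#' [confint.varcomp()].
#'
#' @param formula a nesting formula `response ~ patient/fraction`, e.g.
#'   `error_mm ~ patient_id/fraction`.
#' @param data data frame containing the variables of `formula`.
#' @param level confidence level for the intervals computed at fit time.
#' @param ci_method `"profile"` (default), `"wald"`, or `"none"`.
#' @param control optional list: `reltol`, `maxit` (optimizer),
#'   `boundary_tol` (relative variance floor treated as a collapse).
#' @return An object of class `"varcomp"` with components `M`, `sigma`
#'   (named SDs in mm), `vcomp` (variances), `se_M`, `ci`, `logREML`,
#'   `boundary`, `grad_norm`, `counts`, and supporting data for the methods:
#'   [coef()], [confint()], [summary()], [fitted()], [residuals()],
#'   [predict()], [simulate()], [plot()], [logLik()], [random_effects()],
#'   [overall_mean_test()].
#' @references The nested decomposition of setup errors into patient-,
#'   fraction- and residual-level SDs and its use for margin calculation
#'   follow the variance-component approach standard in radiotherapy QA.
#' @export
#' @examples
#' d <- simulate_errors(simulation_spec(n_patients = 6, n_fractions = 4,
#'                                      frames_per_field = 8, seed = 2))
#' fit <- varcomp(error_mm ~ patient_id/fraction, d)
#' fit
varcomp <- function(formula, data, level = 0.95,
                    ci_method = c("profile", "wald", "none"),
                    control = list()) {
  ci_method <- match.arg(ci_method)
  .check_scalar(level, "level", min = 0, max = 1)
  vars <- all.vars(formula)
  if (length(vars) != 3L || length(formula) != 3L)
    stop_invalid("formula", "must have the form response ~ patient/fraction")
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars))
    stop_invalid("data", paste("missing variables:",
                               paste(missing_vars, collapse = ", ")))
  y <- data[[vars[1]]]
  patient <- as.character(data[[vars[2]]])
  fraction <- as.character(data[[vars[3]]])
  if (!is.numeric(y) || any(!is.finite(y)))
    stop_invalid(vars[1], "response must be finite numeric")
  if (length(y) < 3L)
    stop_invalid("data", "need at least 3 observations")

  cells <- .vc_cells(y, patient, fraction)
  .vc_check_identifiable(cells)

  counts <- list(n_obs = cells$n_obs, n_patients = cells$n_patients,
                 n_cells = cells$n_cells,
                 frames_per_cell = range(cells$n))

  # Degenerate zero-variance data: REML diverges as ve -> 0, so report the
  # exact limit directly.
  if (var(y) < .Machine$double.eps * max(abs(y), 1)^2) {
    fit <- list(
      M = y[1], se_M = 0,
      sigma = c(sigma_pt = 0, sigma_fr = 0, sigma_intra = 0),
      vcomp = c(va = 0, vb = 0, ve = 0),
      logREML = Inf, n2 = -Inf,
      boundary = c(va = TRUE, vb = TRUE, ve = TRUE),
      grad_norm = 0, convergence = 0L, degenerate = TRUE
    )
  } else {
    core <- .vc_reml(cells, control = control)
    fit <- list(
      M = core$M, se_M = sqrt(core$varM),
      sigma = c(sigma_pt = sqrt(unname(core$v["va"])),
                sigma_fr = sqrt(unname(core$v["vb"])),
                sigma_intra = sqrt(unname(core$v["ve"]))),
      vcomp = unname(core$v), logREML = -core$n2 / 2, n2 = core$n2,
      boundary = c(core$boundary, ve = FALSE),
      grad_norm = core$grad_norm, convergence = core$convergence,
      degenerate = FALSE
    )
    names(fit$vcomp) <- c("va", "vb", "ve")
    if (fit$convergence != 0L)
      stop_convergence(sprintf(
        "REML optimizer did not converge (code %d, |grad| = %.3g)",
        fit$convergence, fit$grad_norm),
        trace = fit)
  }

  obj <- structure(c(fit, list(
    call = match.call(), formula = formula, level = level,
    ci_method = ci_method, cells = cells, counts = counts,
    frame = data.frame(y = y, patient = patient, fraction = fraction,
                       cell = paste(patient, fraction, sep = "\r"),
                       stringsAsFactors = FALSE)
  )), class = "varcomp")

  obj$ci <- if (ci_method == "none") NULL
            else .vc_ci(obj, level = level, method = ci_method)
  obj$blup <- .vc_blups(obj)
  obj
}

.vc_check_identifiable <- function(cells) {
  if (cells$n_patients < 2L)
    stop_invalid("data", paste(
      "inter-patient SD is unidentifiable with a single patient;",
      "provide observations from >= 2 patients"))
  per_pat_cells <- tabulate(cells$pidx, cells$n_patients)
  if (!any(per_pat_cells >= 2L))
    stop_invalid("data", paste(
      "inter-fraction SD is unidentifiable: no patient has >= 2 fractions"))
  if (!any(cells$n >= 2L))
    stop_invalid("data", paste(
      "intra-fraction SD is unidentifiable: every fraction has a single",
      "observation"))
}

# Confidence intervals: profile restricted likelihood for the SDs, Wald
# for the mean. Returns a 4x2 matrix with attributes for boundary flags.
.vc_ci <- function(object, level, method = c("profile", "wald"),
                   parm = c("M", "sigma_pt", "sigma_fr", "sigma_intra")) {
  method <- match.arg(method)
  parm <- match.arg(parm, several.ok = TRUE)
  est <- c(M = object$M, object$sigma)
  ci <- matrix(NA_real_, length(parm), 2,
               dimnames = list(parm, c("lower", "upper")))
  flags <- setNames(rep("two-sided", length(parm)), parm)

  if (level <= 0) {      # degenerate interval at the point estimate
    ci[, 1] <- est[parm]; ci[, 2] <- est[parm]
    attr(ci, "flags") <- flags
    attr(ci, "level") <- level
    return(ci)
  }

  z <- qnorm((1 + level) / 2)
  if ("M" %in% parm) {
    ci["M", ] <- object$M + c(-1, 1) * z * object$se_M
  }

  sd_parm <- setdiff(parm, "M")
  if (length(sd_parm) && object$degenerate) {
    ci[sd_parm, ] <- 0
    attr(ci, "flags") <- flags
    attr(ci, "level") <- level
    return(ci)
  }

  map <- c(sigma_pt = "va", sigma_fr = "vb", sigma_intra = "ve")
  for (p in sd_parm) {
    w <- map[[p]]
    hat <- est[[p]]
    if (method == "wald") {
      # symmetric interval on the SD scale from the profile curvature
      h <- max(hat, 0.05) * 0.05
      f <- function(s) .vc_profile_n2(object$cells, w, s^2,
                                      start = object$vcomp)
      d2 <- (f(hat + h) - 2 * object$n2 + f(max(hat - h, h / 10))) / h^2
      se <- if (is.finite(d2) && d2 > 0) sqrt(2 / d2) else NA_real_
      ci[p, ] <- pmax(hat + c(-1, 1) * z * se, 0)
      if (ci[p, 1] == 0) flags[p] <- "lower-at-zero"
      next
    }
    pci <- .vc_profile_ci(object, w, hat, level)
    ci[p, ] <- pci$interval
    flags[p] <- pci$flag
  }
  attr(ci, "flags") <- flags
  attr(ci, "level") <- level
  ci
}

# Profile-likelihood interval for one SD parameter
.vc_profile_ci <- function(object, w, hat, level) {
  target <- object$n2 + qchisq(level, 1)
  start <- setNames(object$vcomp, c("va", "vb", "ve"))
  f <- function(s) .vc_profile_n2(object$cells, w, s^2, start = start) - target

  scale <- max(hat, sqrt(sum(object$vcomp)) / 4, 1e-3)

  # upper limit: expand until the profile crosses the cutoff
  hi <- hat + scale
  for (i in 1:60) {
    if (f(hi) > 0) break
    hi <- hat + (hi - hat) * 2
  }
  upper <- if (f(hi) > 0)
    uniroot(f, c(hat, hi), tol = 1e-6 * scale)$root else Inf

  # lower limit
  if (hat <= .Machine$double.eps) {
    return(list(interval = c(0, upper), flag = "boundary-one-sided"))
  }
  flag <- "two-sided"
  f0 <- f(hat * 1e-6)
  lower <- if (f0 <= 0) {
    flag <- "lower-at-zero"
    0
  } else uniroot(f, c(hat * 1e-6, hat), tol = 1e-6 * scale)$root
  list(interval = c(lower, upper), flag = flag)
}

# Empirical BLUPs of the patient and fraction effects at the REML estimates
.vc_blups <- function(object) {
  cells <- object$cells
  v <- object$vcomp
  if (object$degenerate || sum(v) == 0) {
    pa <- setNames(rep(0, cells$n_patients), cells$patient_levels)
    cl <- setNames(rep(0, cells$n_cells),
                   paste(cells$cell_patient, cells$cell_fraction, sep = "\r"))
    return(list(patient = pa, cell = cl))
  }
  va <- v[["va"]]; vb <- v[["vb"]]; ve <- v[["ve"]]
  d <- ve + cells$n * vb
  t_j <- cells$n / d; s_j <- cells$S / d
  per <- rowsum(cbind(t_j, s_j), cells$pidx, reorder = TRUE)
  tp <- per[, 1]; sp <- per[, 2]
  a_hat <- va * (sp - object$M * tp) / (1 + va * tp)
  b_hat <- vb / d * (cells$S - cells$n * object$M - cells$n * a_hat[cells$pidx])
  list(patient = setNames(as.numeric(a_hat), cells$patient_levels),
       cell = setNames(as.numeric(b_hat),
                       paste(cells$cell_patient, cells$cell_fraction,
                             sep = "\r")))
}
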
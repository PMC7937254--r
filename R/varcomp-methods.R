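# S3 methods for "varcomp" fits

#' @export
print.varcomp <- function(x, digits = 3, ...) {
  cat("Nested variance-component fit (REML)\n")
  cat("  call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("  %d observations, %d patients, %d patient:fraction cells\n",
              x$counts$n_obs, x$counts$n_patients, x$counts$n_cells))
  est <- c("overall mean M" = x$M,
           "inter-patient SD (Sigma_pt)" = x$sigma[["sigma_pt"]],
           "inter-fraction SD (sigma_fr)" = x$sigma[["sigma_fr"]],
           "intra-fraction SD (sigma_intra)" = x$sigma[["sigma_intra"]])
  lab <- format(names(est))
  for (i in seq_along(est)) {
    line <- sprintf("  %s %8.*f mm", lab[i], digits, est[i])
    if (!is.null(x$ci)) {
      key <- c("M", "sigma_pt", "sigma_fr", "sigma_intra")[i]
      line <- sprintf("%s  [%.*f, %.*f]", line,
                      digits, x$ci[key, 1], digits, x$ci[key, 2])
    }
    cat(line, "\n")
  }
  if (!is.null(x$ci))
    cat(sprintf("  (%.0f%% CIs: %s for SDs, Wald for M)\n",
                100 * attr(x$ci, "level"), x$ci_method))
  if (any(x$boundary))
    cat("  note: boundary estimate(s):",
        paste(names(x$boundary)[x$boundary], collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.varcomp <- function(object, ...) {
  tab <- data.frame(
    estimate_mm = c(object$M, unname(object$sigma)),
    lower = if (is.null(object$ci)) NA_real_ else object$ci[, 1],
    upper = if (is.null(object$ci)) NA_real_ else object$ci[, 2],
    row.names = c("overall_mean_M", "sigma_pt", "sigma_fr", "sigma_intra")
  )
  out <- list(call = object$call, table = tab, level = object$level,
              ci_method = object$ci_method, counts = object$counts,
              logREML = object$logREML, grad_norm = object$grad_norm,
              boundary = object$boundary,
              mean_excludes_zero = overall_mean_test(object))
  class(out) <- "summary.varcomp"
  out
}

#' @export
print.summary.varcomp <- function(x, digits = 3, ...) {
  cat("Variance component analysis of breath-hold positional errors (REML)\n")
  cat("  call: ", deparse(x$call), "\n\n", sep = "")
  printCoefmat(as.matrix(x$table), digits = digits, na.print = "-")
  cat(sprintf("\n  %d observations | %d patients | %d cells | logREML %.2f | |grad| %.2g\n",
              x$counts$n_obs, x$counts$n_patients, x$counts$n_cells,
              x$logREML, x$grad_norm))
  cat(sprintf("  overall mean %s 0 at the %.0f%% level\n",
              if (x$mean_excludes_zero) "differs from" else
                "does not significantly deviate from",
              100 * x$level))
  invisible(x)
}

#' @importFrom stats printCoefmat
#' @export
coef.varcomp <- function(object, ...) {
  c(mean_M = object$M, object$sigma)
}

#' Confidence intervals for a variance-component fit
#'
#' Profile restricted-likelihood intervals for the three SDs and a Wald
#' interval for the overall mean (the default), or a parametric bootstrap
#' (percentile intervals from refits of simulated data sets).
#'
#' @param object a [varcomp()] fit.
#' @param parm parameters to include (default all four).
#' @param level confidence level; `level = 0` gives degenerate intervals at
#'   the point estimates.
#' @param method `"profile"`, `"wald"`, or `"bootstrap"`.
#' @param nsim bootstrap replicates (when `method = "bootstrap"`).
#' @param seed optional seed for the bootstrap.
#' @param ... unused.
#' @return Matrix with `lower`/`upper` columns; `attr(, "flags")` records
#'   one-sided/boundary intervals.
#' @export
confint.varcomp <- function(object,
                            parm = c("M", "sigma_pt", "sigma_fr",
                                     "sigma_intra"),
                            level = 0.95,
                            method = c("profile", "wald", "bootstrap"),
                            nsim = 200, seed = NULL, ...) {
  method <- match.arg(method)
  parm <- match.arg(parm, several.ok = TRUE)
  .check_scalar(level, "level", min = 0, max = 1)
  if (method != "bootstrap")
    return(.vc_ci(object, level = level, method = method, parm = parm))

  if (!is.null(seed)) set.seed(as.integer(seed))
  sims <- simulate(object, nsim = nsim)
  draws <- matrix(NA_real_, nsim, 4,
                  dimnames = list(NULL, c("M", "sigma_pt", "sigma_fr",
                                          "sigma_intra")))
  fr <- object$frame
  for (i in seq_len(nsim)) {
    fi <- tryCatch(
      varcomp(y ~ patient/fraction,
              data.frame(y = sims[[i]], patient = fr$patient,
                         fraction = fr$fraction),
              ci_method = "none"),
      error = function(e) NULL)
    if (!is.null(fi)) draws[i, ] <- c(fi$M, unname(fi$sigma))
  }
  probs <- c((1 - level) / 2, (1 + level) / 2)
  ci <- t(apply(draws[, parm, drop = FALSE], 2, quantile, probs = probs,
                na.rm = TRUE))
  colnames(ci) <- c("lower", "upper")
  attr(ci, "flags") <- setNames(rep("bootstrap-percentile", length(parm)),
                                parm)
  attr(ci, "level") <- level
  attr(ci, "n_ok") <- sum(stats::complete.cases(draws))
  ci
}

#' @export
logLik.varcomp <- function(object, ...) {
  structure(object$logREML, df = 4L, nobs = object$counts$n_obs,
            class = "logLik")
}

#' @export
nobs.varcomp <- function(object, ...) object$counts$n_obs

#' @export
fitted.varcomp <- function(object, ...) {
  fr <- object$frame
  unname(object$M + object$blup$patient[fr$patient] +
           object$blup$cell[fr$cell])
}

#' Residuals of a variance-component fit
#'
#' `"conditional"` residuals subtract the empirical BLUPs of the patient and
#' fraction effects (estimating the intra-fraction noise); `"marginal"`
#' residuals subtract only the overall mean.
#'
#' @param object a [varcomp()] fit.
#' @param type `"conditional"` (default) or `"marginal"`.
#' @param ... unused.
#' @export
residuals.varcomp <- function(object, type = c("conditional", "marginal"),
                              ...) {
  type <- match.arg(type)
  y <- object$frame$y
  if (type == "marginal") return(y - object$M)
  unname(y - fitted(object))
}

#' Predict mean error for patient/fraction combinations
#'
#' Returns the conditional mean `M + a_patient + b_patient:fraction` using
#' the empirical BLUPs; unknown patients or fractions contribute 0 (the
#' population mean is returned for entirely new patients).
#'
#' @param object a [varcomp()] fit.
#' @param newdata data frame with the patient and fraction columns of the
#'   original formula; `NULL` returns the fitted values.
#' @param ... unused.
#' @export
predict.varcomp <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  vars <- all.vars(object$formula)
  missing_vars <- setdiff(vars[2:3], names(newdata))
  if (length(missing_vars))
    stop_invalid("newdata", paste("missing variables:",
                                  paste(missing_vars, collapse = ", ")))
  pat <- as.character(newdata[[vars[2]]])
  cell <- paste(pat, as.character(newdata[[vars[3]]]), sep = "\r")
  a <- object$blup$patient[pat]; a[is.na(a)] <- 0
  b <- object$blup$cell[cell]; b[is.na(b)] <- 0
  unname(object$M + a + b)
}

#' Simulate from a fitted variance-component model
#'
#' Parametric simulation over the observed design: new patient, fraction and
#' residual effects are drawn at the REML estimates.
#'
#' @param object a [varcomp()] fit.
#' @param nsim number of response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A data frame with `nsim` columns (`sim_1`, ...), one row per
#'   original observation.
#' @export
simulate.varcomp <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  fr <- object$frame
  pat <- factor(fr$patient); cell <- factor(fr$cell)
  P <- nlevels(pat); Cn <- nlevels(cell)
  s <- sqrt(object$vcomp)
  out <- vapply(seq_len(nsim), function(i) {
    a <- rnorm(P, 0, s[["va"]])
    b <- rnorm(Cn, 0, s[["vb"]])
    e <- rnorm(nrow(fr), 0, s[["ve"]])
    object$M + a[as.integer(pat)] + b[as.integer(cell)] + e
  }, numeric(nrow(fr)))
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Per-patient and per-fraction random effects (empirical BLUPs)
#'
#' @param object a [varcomp()] fit.
#' @return List with named vectors `patient` and `fraction` (keyed
#'   `patient:fraction`).
#' @export
random_effects <- function(object) {
  if (!inherits(object, "varcomp"))
    stop_invalid("object", "must be a varcomp fit")
  cellnames <- sub("\r", ":", names(object$blup$cell), fixed = TRUE)
  list(patient = object$blup$patient,
       fraction = setNames(object$blup$cell, cellnames))
}

#' @export
plot.varcomp <- function(x, ...) {
  fr <- x$frame
  boxplot(fr$y ~ factor(fr$patient), xlab = "patient",
          ylab = "positional error (mm)",
          main = "Breath-hold chest-wall errors by patient", ...)
  abline(h = x$M, col = "red3", lwd = 2)
  abline(h = 0, col = "grey40", lty = 3)
  mtext(sprintf("overall mean M = %.2f mm", x$M), side = 3, line = 0.2,
        col = "red3", cex = 0.8)
  invisible(x)
}

#' Does the overall mean differ from zero?
#'
#' `TRUE` iff 0 lies strictly outside the confidence interval for the overall
#' mean M; an interval endpoint equal to 0 counts as containing it.
#'
#' @param object a [varcomp()] fit (fitted with intervals).
#' @return Logical flag.
#' @export
overall_mean_test <- function(object) {
  if (!inherits(object, "varcomp"))
    stop_invalid("object", "must be a varcomp fit")
  ci <- object$ci
  if (is.null(ci) || !"M" %in% rownames(ci))
    ci <- .vc_ci(object, level = object$level, method = "wald", parm = "M")
  !(ci["M", 1] <= 0 && 0 <= ci["M", 2])
}
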
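# PTV margin from variance components: the van Herk recipe with the
# inter-fraction component re-apportioned between its systematic and random
# roles according to the number of fractions N:
#
#   Sigma_eff^2 = Sigma_pt^2 + sigma_fr^2 / N
#   sigma_eff^2 = (1 - 1/N) sigma_fr^2 + sigma_intra^2
#   margin      = 2.5 Sigma_eff + 0.7 sigma_eff
#
# The margin is one-dimensional: it applies along the measurement direction
# in the beam's-eye-view plane, not as an isotropic 3-D expansion.

#' Effective systematic and random errors for N fractions
#'
#' With a finite number of fractions N, the inter-fraction variation acts
#' partly as a systematic error (its mean over N fractions does not average
#' to zero) and partly as a random error. The effective components are
#' `Sigma_eff = sqrt(Sigma_pt^2 + sigma_fr^2 / N)` and
#' `sigma_eff = sqrt((1 - 1/N) * sigma_fr^2 + sigma_intra^2)`.
#'
#' @param sigma_pt inter-patient SD, mm (>= 0).
#' @param sigma_fr inter-fraction SD, mm (>= 0).
#' @param sigma_intra intra-fraction SD, mm (>= 0).
#' @param n_fractions number of treatment fractions N (>= 1).
#' @return Named numeric vector `c(Sigma_eff = , sigma_eff = )` in mm.
#' @export
#' @examples
#' effective_errors(0.82, 1.19, 1.63, n_fractions = 16)  # ~0.87, ~2.00 mm
effective_errors <- function(sigma_pt, sigma_fr, sigma_intra, n_fractions) {
  .check_scalar(sigma_pt, "sigma_pt", min = 0)
  .check_scalar(sigma_fr, "sigma_fr", min = 0)
  .check_scalar(sigma_intra, "sigma_intra", min = 0)
  .check_scalar(n_fractions, "n_fractions", min = 1)
  c(Sigma_eff = sqrt(sigma_pt^2 + sigma_fr^2 / n_fractions),
    sigma_eff = sqrt((1 - 1 / n_fractions) * sigma_fr^2 + sigma_intra^2))
}

#' PTV margin from effective errors
#'
#' Linear margin recipe `c_sys * Sigma_eff + c_rand * sigma_eff`. The default
#' coefficients 2.5 and 0.7 ensure a 95% minimum dose to the CTV for 90% of
#' patients (the van Herk criterion); they are parameters so alternative
#' recipes can be explored.
#'
#' @param Sigma_eff effective systematic error, mm (>= 0).
#' @param sigma_eff effective random error, mm (>= 0).
#' @param c_sys systematic multiplier (default 2.5, >= 0).
#' @param c_rand random multiplier (default 0.7, >= 0).
#' @return Margin in mm.
#' @export
#' @examples
#' ptv_margin(0.8723, 1.9961)  # ~3.58 mm
ptv_margin <- function(Sigma_eff, sigma_eff, c_sys = 2.5, c_rand = 0.7) {
  .check_scalar(Sigma_eff, "Sigma_eff", min = 0)
  .check_scalar(sigma_eff, "sigma_eff", min = 0)
  .check_scalar(c_sys, "c_sys", min = 0)
  .check_scalar(c_rand, "c_rand", min = 0)
  c_sys * Sigma_eff + c_rand * sigma_eff
}

#' Margin report from fitted variance components
#'
#' Composes [effective_errors()] and [ptv_margin()] into a report mirroring
#' the standard error/margin table: the breath-hold error block (component
#' SDs with CIs when available), the effective systematic/random block, and
#' the PTV margin for the given number of fractions.
#'
#' @param components a [varcomp()] fit, or a named numeric vector containing
#'   `sigma_pt`, `sigma_fr`, `sigma_intra` (optionally `mean_M`), in mm.
#' @param n_fractions number of treatment fractions N (>= 1).
#' @param c_sys,c_rand margin multipliers, see [ptv_margin()].
#' @return An object of class `"margin_report"`: list with `components`
#'   (data frame, mm), `n_fractions`, `Sigma_eff`, `sigma_eff`,
#'   `ptv_margin_mm`, `coefficients` and a `scope` note (the margin is
#'   one-directional in the beam's-eye-view plane).
#' @export
#' @examples
#' margin_report(c(sigma_pt = 0.82, sigma_fr = 1.19, sigma_intra = 1.63),
#'               n_fractions = 16)
margin_report <- function(components, n_fractions, c_sys = 2.5,
                          c_rand = 0.7) {
  if (inherits(components, "varcomp")) {
    sds <- components$sigma
    ci <- components$ci
    comp <- data.frame(
      estimate_mm = c(sds[["sigma_pt"]], sds[["sigma_fr"]],
                      sds[["sigma_intra"]], components$M),
      lower = if (is.null(ci)) NA_real_ else
        ci[c("sigma_pt", "sigma_fr", "sigma_intra", "M"), 1],
      upper = if (is.null(ci)) NA_real_ else
        ci[c("sigma_pt", "sigma_fr", "sigma_intra", "M"), 2],
      row.names = c("sigma_pt", "sigma_fr", "sigma_intra", "overall_mean_M"))
  } else {
    if (!is.numeric(components) ||
        !all(c("sigma_pt", "sigma_fr", "sigma_intra") %in% names(components)))
      stop_invalid("components", paste(
        "must be a varcomp fit or a named vector with sigma_pt, sigma_fr,",
        "sigma_intra"))
    sds <- components
    comp <- data.frame(
      estimate_mm = c(sds[["sigma_pt"]], sds[["sigma_fr"]],
                      sds[["sigma_intra"]],
                      if ("mean_M" %in% names(sds)) sds[["mean_M"]]
                      else NA_real_),
      lower = NA_real_, upper = NA_real_,
      row.names = c("sigma_pt", "sigma_fr", "sigma_intra", "overall_mean_M"))
  }

  eff <- effective_errors(sds[["sigma_pt"]], sds[["sigma_fr"]],
                          sds[["sigma_intra"]], n_fractions)
  structure(list(
    components = comp,
    n_fractions = n_fractions,
    Sigma_eff = unname(eff["Sigma_eff"]),
    sigma_eff = unname(eff["sigma_eff"]),
    ptv_margin_mm = ptv_margin(eff[["Sigma_eff"]], eff[["sigma_eff"]],
                               c_sys, c_rand),
    coefficients = c(c_sys = c_sys, c_rand = c_rand),
    units = "mm",
    scope = "one direction in the beam's-eye-view plane (not isotropic 3-D)"
  ), class = "margin_report")
}

#' @export
print.margin_report <- function(x, digits = 2, ...) {
  cat("PTV margin from breath-hold variance components (all values mm)\n")
  cat("Breath-hold error components\n")
  comp <- x$components
  labs <- c("  Inter-patient (Sigma_pt)", "  Inter-fraction (sigma_fr)",
            "  Intra-fraction (sigma_intra)", "  Overall mean (M)")
  for (i in seq_len(nrow(comp))) {
    if (is.na(comp$estimate_mm[i])) next
    line <- sprintf("%-32s %6.*f", labs[i], digits, comp$estimate_mm[i])
    if (!is.na(comp$lower[i]))
      line <- sprintf("%s  (%.*f to %.*f)", line, digits, comp$lower[i],
                      digits, comp$upper[i])
    cat(line, "\n")
  }
  cat(sprintf("Effective errors at N = %g fractions\n", x$n_fractions))
  cat(sprintf("%-32s %6.*f\n", "  Effective systematic (Sigma_eff)",
              digits, x$Sigma_eff))
  cat(sprintf("%-32s %6.*f\n", "  Effective random (sigma_eff)",
              digits, x$sigma_eff))
  cat(sprintf("%-32s %6.*f   (= %.1f Sigma_eff + %.1f sigma_eff)\n",
              "PTV margin", digits, x$ptv_margin_mm,
              x$coefficients[["c_sys"]], x$coefficients[["c_rand"]]))
  cat("Scope:", x$scope, "\n")
  invisible(x)
}

#' @export
as.data.frame.margin_report <- function(x, ...) {
  data.frame(
    quantity = c(rownames(x$components), "Sigma_eff", "sigma_eff",
                 "ptv_margin"),
    value_mm = c(x$components$estimate_mm, x$Sigma_eff, x$sigma_eff,
                 x$ptv_margin_mm),
    lower = c(x$components$lower, NA, NA, NA),
    upper = c(x$components$upper, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}
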
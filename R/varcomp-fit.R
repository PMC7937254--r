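# REML for the two-level nested random-effect model
#
#   y[p,f,k] = M + a[p] + b[p,f] + e[p,f,k]
#   a ~ N(0, va), b ~ N(0, vb), e ~ N(0, ve), independent
#
# The restricted likelihood is evaluated from per-fraction sufficient
# statistics (n, sum y, sum y^2 per patient:fraction cell), so the cost is
# O(#cells) per evaluation regardless of the number of frames. For patient p
# with fraction cells j: d_j = ve + n_j vb,
#   t_p = sum n_j/d_j,  s_p = sum S_j/d_j,
#   q_p = sum(Q_j/ve - vb S_j^2/(ve d_j)),
#   log|V_p| = sum((n_j-1) log ve + log d_j) + log(1 + va t_p)
# and with den_p = 1 + va t_p,
#   1'V_p^-1 1 = t_p/den_p,  1'V_p^-1 y = s_p/den_p,
#   y'V_p^-1 y = q_p - va s_p^2/den_p.
# The fixed mean M is profiled out; -2 log restricted likelihood is
#   sum log|V_p| + log(sum t_p/den_p) + sum y'V_p^-1 y
#     - (sum s_p/den_p)^2 / (sum t_p/den_p) + (N-1) log(2 pi).

# Per-cell sufficient statistics grouped by patient
.vc_cells <- function(y, patient, fraction) {
  pid <- factor(patient)
  cell <- factor(paste(as.character(pid), as.character(fraction),
                       sep = "\r"))
  ci <- as.integer(cell)
  n <- as.numeric(tabulate(ci, nlevels(cell)))
  S <- as.numeric(rowsum(y, ci, reorder = TRUE))
  Q <- as.numeric(rowsum(y^2, ci, reorder = TRUE))
  # patient index of each cell
  first <- match(seq_len(nlevels(cell)), ci)
  pidx <- as.integer(pid)[first]
  list(n = n, S = S, Q = Q, pidx = pidx,
       n_obs = length(y), n_patients = nlevels(pid), n_cells = nlevels(cell),
       patient_levels = levels(pid),
       cell_patient = as.character(pid)[first],
       cell_fraction = as.character(fraction)[first])
}

# -2 * restricted log-likelihood; also returns the profiled mean and its
# variance at the given variance components
.vc_n2rl <- function(va, vb, ve, cells, details = FALSE) {
  if (ve <= 0) return(if (details) list(n2 = Inf) else Inf)
  va <- max(va, 0); vb <- max(vb, 0)
  d <- ve + cells$n * vb
  t_j <- cells$n / d
  s_j <- cells$S / d
  q_j <- cells$Q / ve - vb * cells$S^2 / (ve * d)
  ld_j <- (cells$n - 1) * log(ve) + log(d)
  per <- rowsum(cbind(t_j, s_j, q_j, ld_j), cells$pidx, reorder = TRUE)
  tp <- per[, 1]; sp <- per[, 2]; qp <- per[, 3]; ldp <- per[, 4]
  den <- 1 + va * tp
  Tsum <- sum(tp / den)
  Syv <- sum(sp / den)
  yPy <- sum(qp - va * sp^2 / den)
  n2 <- sum(ldp) + sum(log(den)) + log(Tsum) + yPy - Syv^2 / Tsum +
    (cells$n_obs - 1) * log(2 * pi)
  if (!details) return(n2)
  list(n2 = n2, M = Syv / Tsum, varM = 1 / Tsum,
       tp = tp, sp = sp, den = den)
}

# Method-of-moments starting values (crude, truncated at a floor)
.vc_start <- function(cells) {
  vy <- {
    N <- cells$n_obs
    (sum(cells$Q) - sum(cells$S)^2 / N) / max(N - 1, 1)
  }
  floor_v <- max(vy, .Machine$double.eps) * 1e-4
  ve0 <- {
    within_ss <- sum(cells$Q - cells$S^2 / cells$n)
    dfw <- cells$n_obs - cells$n_cells
    if (dfw > 0) within_ss / dfw else vy / 3
  }
  cm <- cells$S / cells$n
  vb0 <- if (cells$n_cells > 1)
    max(var(cm) - ve0 * mean(1 / cells$n), floor_v) else floor_v
  pm <- rowsum(cells$S, cells$pidx) / rowsum(cells$n, cells$pidx)
  Fbar <- cells$n_cells / cells$n_patients
  va0 <- if (cells$n_patients > 1)
    max(var(as.numeric(pm)) - vb0 / Fbar, floor_v) else floor_v
  c(va = va0, vb = vb0, ve = max(ve0, floor_v))
}

# Optimize -2lR over log-variances; `active` marks which of (va, vb) are
# free, ve is always free. Inactive components are fixed at `fixed`.
.vc_optim <- function(cells, start, active = c(va = TRUE, vb = TRUE),
                      fixed = c(va = 0, vb = 0), control = list()) {
  reltol <- control$reltol %||% 1e-13
  maxit <- control$maxit %||% 5000
  build <- function(par) {
    k <- 1L
    va <- if (active["va"]) { v <- exp(par[k]); k <- k + 1L; v } else fixed["va"]
    vb <- if (active["vb"]) { v <- exp(par[k]); k <- k + 1L; v } else fixed["vb"]
    ve <- exp(par[k])
    c(va = unname(va), vb = unname(vb), ve = unname(ve))
  }
  obj <- function(par) {
    v <- build(par)
    n2 <- .vc_n2rl(v[1], v[2], v[3], cells)
    if (!is.finite(n2)) 1e300 else n2
  }
  par0 <- log(c(start[c("va", "vb")][active], start["ve"]))
  fit <- optim(par0, obj, method = "Nelder-Mead",
               control = list(reltol = reltol, maxit = maxit))
  polish <- tryCatch(
    optim(fit$par, obj, method = "BFGS",
          control = list(reltol = reltol, maxit = 500,
                         ndeps = rep(1e-7, length(fit$par)))),
    error = function(e) fit)
  if (is.finite(polish$value) && polish$value <= fit$value) fit <- polish
  fit2 <- optim(fit$par, obj, method = "Nelder-Mead",
                control = list(reltol = reltol, maxit = maxit))
  if (fit2$value <= fit$value) fit <- fit2
  # coordinate-wise Brent sweeps: NM/BFGS stall ~1e-6 from the optimum along
  # flat directions (small components); this cleans up the last digits
  par <- fit$par; val <- fit$value
  for (sweep in 1:3) {
    moved <- FALSE
    for (k in seq_along(par)) {
      o <- optimize(function(x) { p <- par; p[k] <- x; obj(p) },
                    interval = par[k] + c(-0.5, 0.5), tol = 1e-12)
      if (o$objective < val - 1e-13) {
        par[k] <- o$minimum; val <- o$objective; moved <- TRUE
      }
    }
    if (!moved) break
  }
  list(v = build(par), n2 = val, par = par,
       convergence = fit$convergence)
}

# Full fit with boundary handling: fit with all components free; when a
# variance collapses toward the floor, refit with it pinned to zero and keep
# the better restricted likelihood.
.vc_reml <- function(cells, control = list()) {
  start <- .vc_start(cells)
  vy <- sum(cells$Q) / cells$n_obs - (sum(cells$S) / cells$n_obs)^2
  btol <- (control$boundary_tol %||% 1e-7) * max(vy, .Machine$double.eps)

  fits <- list(.vc_optim(cells, start, control = control))
  v <- fits[[1]]$v
  collapse <- c(va = v[["va"]] < btol, vb = v[["vb"]] < btol)
  if (collapse["va"])
    fits <- c(fits, list(.vc_optim(cells, start,
                                   active = c(va = FALSE, vb = TRUE),
                                   control = control)))
  if (collapse["vb"])
    fits <- c(fits, list(.vc_optim(cells, start,
                                   active = c(va = TRUE, vb = FALSE),
                                   control = control)))
  if (all(collapse))
    fits <- c(fits, list(.vc_optim(cells, start,
                                   active = c(va = FALSE, vb = FALSE),
                                   control = control)))
  n2s <- vapply(fits, `[[`, numeric(1), "n2")
  best <- fits[[which.min(n2s)]]
  v <- best$v
  boundary <- c(va = v[["va"]] < btol, vb = v[["vb"]] < btol)
  if (boundary[["va"]]) v[["va"]] <- 0
  if (boundary[["vb"]]) v[["vb"]] <- 0

  det <- .vc_n2rl(v[[1]], v[[2]], v[[3]], cells, details = TRUE)

  # numerical gradient of -2lR on the log scale of the free components
  grad <- rep(NA_real_, 3)
  free <- c(!boundary, ve = TRUE)
  h <- 1e-5
  vals <- unname(v)
  for (i in which(free)) {
    vp <- vals; vm <- vals
    vp[i] <- vals[i] * exp(h); vm[i] <- vals[i] * exp(-h)
    grad[i] <- (.vc_n2rl(vp[1], vp[2], vp[3], cells) -
                  .vc_n2rl(vm[1], vm[2], vm[3], cells)) / (2 * h)
  }
  gnorm <- sqrt(sum(grad[free]^2))

  list(v = v, n2 = det$n2, M = det$M, varM = det$varM,
       boundary = boundary, grad_norm = gnorm,
       convergence = best$convergence)
}

# Profile -2lR for one component fixed at variance `vfix`
.vc_profile_n2 <- function(cells, which_par, vfix, start, control = list()) {
  stopifnot(which_par %in% c("va", "vb", "ve"))
  reltol <- control$reltol %||% 1e-11
  floor_v <- max(start["ve"], .Machine$double.eps) * 1e-10
  if (which_par == "ve") {
    if (vfix <= 0) return(Inf)
    obj <- function(par) {
      n2 <- .vc_n2rl(exp(par[1]), exp(par[2]), vfix, cells)
      if (!is.finite(n2)) 1e300 else n2
    }
    par0 <- log(pmax(start[c("va", "vb")], floor_v))
  } else {
    others <- setdiff(c("va", "vb"), which_par)
    obj <- function(par) {
      vo <- exp(par[1]); ve <- exp(par[2])
      va <- if (which_par == "va") vfix else vo
      vb <- if (which_par == "vb") vfix else vo
      n2 <- .vc_n2rl(va, vb, ve, cells)
      if (!is.finite(n2)) 1e300 else n2
    }
    par0 <- log(pmax(c(start[others], start["ve"]), floor_v))
  }
  fit <- optim(par0, obj, method = "Nelder-Mead",
               control = list(reltol = reltol, maxit = 2000))
  fit$value
}
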
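#' Weights, bounds and optimizer settings for the constrained inversion
#'
#' `w` weights the susceptibility-consistency penalty (signal^2/ppm^2) and
#' `p` the R2'-consistency penalty (signal^2 s^2). `"auto"` uses
#' inverse-variance weighting: the per-voxel noise variance, estimated from
#' second differences of the echo trains, divided by the squared prior
#' uncertainty scale (`chi_floor` ppm, `r2p_floor` 1/s). Penalties thus
#' vanish for noiseless data (where the echoes identify the parameters on
#' their own) and grow with the noise level, trading variance against the
#' small bias of the measured priors.
#'
#' Because the mono-exponential R2 prior carries a small curvature bias that
#' the inversion would otherwise amplify, R2 is by default refined by the
#' fit as well: it enters as a fifth bounded parameter initialised at, and
#' softly penalised toward, its measured prior — exactly parallel to how the
#' measured R2' and susceptibility enter as penalties rather than hard
#' constraints. Set `estimate_r2 = FALSE` to pin R2 to the prior and fit
#' only the four canonical unknowns.
#'
#' The CBVv prior likewise acts as a soft penalty on DBV (weight `w_dbv`,
#' scale `dbv_floor`), so all four measured constraints enter the objective
#' the same way; `dbv_equals_cbvv = TRUE` hardens that penalty into an
#' equality.
#'
#' @param w,p Penalty weights (nonnegative numbers) or `"auto"`.
#' @param w_dbv Weight of the CBVv-consistency penalty on DBV (number or
#'   `"auto"`).
#' @param bounds Named list of `c(lower, upper)` for `yv`, `dbv`, `r2p_nh`,
#'   `chi_nb`, `r2`. Defaults span physiological ranges.
#' @param cbva Fixed arterial blood volume fraction used inside the
#'   susceptibility model (not estimated).
#' @param chi_floor,r2p_floor,r2_floor,dbv_floor Prior-uncertainty scales of
#'   the auto-weight heuristic (ppm, 1/s, 1/s, volume fraction).
#' @param max_iter Maximum optimizer iterations per voxel.
#' @param ftol Relative objective convergence tolerance.
#' @param multistart Number of starts over an Yv grid (1 = smart init only).
#' @param estimate_r2 Refine R2 within the fit (soft prior) instead of
#'   fixing it.
#' @param p_r2 Weight of the R2 prior penalty (number or `"auto"`).
#' @param dbv_equals_cbvv If `TRUE`, DBV is pinned to the CBVv prior instead
#'   of being estimated.
#' @return A `fit_weights` list.
#' @export
fit_weights <- function(w = "auto", p = "auto", w_dbv = "auto",
                        bounds = list(yv = c(0.30, 0.98),
                                      dbv = c(0.001, 0.10),
                                      r2p_nh = c(0, 20),
                                      chi_nb = c(-0.2, 0.2),
                                      r2 = c(0.5, 80)),
                        cbva = 0.01,
                        chi_floor = 0.01, r2p_floor = 0.2, r2_floor = 0.2,
                        dbv_floor = 0.005,
                        max_iter = 150L, ftol = 1e-12,
                        multistart = 1L,
                        estimate_r2 = TRUE, p_r2 = "auto",
                        dbv_equals_cbvv = FALSE) {
  if (is.null(bounds$r2)) bounds$r2 <- c(0.5, 80)
  chk <- function(x, nm) {
    if (is.character(x)) {
      if (!identical(x, "auto")) abort(sprintf("`%s` must be numeric or \"auto\".", nm))
    } else if (!is.numeric(x) || x < 0) {
      abort(sprintf("`%s` must be nonnegative.", nm))
    }
    x
  }
  chk(w, "w"); chk(p, "p"); chk(p_r2, "p_r2"); chk(w_dbv, "w_dbv")
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (length(b) != 2L || !all(is.finite(b)) || b[1] >= b[2]) {
      abort(sprintf("Bounds for `%s` must be finite with lower < upper.", nm))
    }
  }
  structure(list(w = w, p = p, p_r2 = p_r2, w_dbv = w_dbv,
                 bounds = bounds, cbva = cbva,
                 chi_floor = chi_floor, r2p_floor = r2p_floor,
                 r2_floor = r2_floor, dbv_floor = dbv_floor,
                 max_iter = as.integer(max_iter), ftol = ftol,
                 multistart = as.integer(multistart),
                 estimate_r2 = estimate_r2,
                 dbv_equals_cbvv = dbv_equals_cbvv),
            class = "fit_weights")
}

# susceptibility model and R2' decomposition on raw parameters (no
# voxel_state overhead inside the optimizer loop)
psi_raw <- function(yv, chi_nb, cbvv, cbva, hct, constants) {
  art <- constants$chi_oxy + hct * constants$delta_chi_do * (1 - constants$sao2)
  ven <- constants$chi_oxy + hct * constants$delta_chi_do * (1 - yv)
  cbva * art + cbvv * ven + (1 - cbva - cbvv) * chi_nb
}

yfun_raw <- function(yv, dbv, r2p_nh, hct, constants) {
  dbv * delta_omega(hct, yv, constants) + r2p_nh
}

# stacked residual with amplitudes profiled out (variable projection);
# a theta of length 5 carries a free R2 (softly anchored to the R2 prior,
# which always arrives via the `r2` argument, with weight p_r2)
qbold_residual <- function(theta, y_fid, y_echo, te_fid, te_echo, tr,
                           r2, dchi_prior, r2p_prior, cbvv_prior,
                           hct, w, p, cbva, constants, p_r2 = 0,
                           w_dbv = 0) {
  yv <- theta[1]; dbv <- theta[2]; r2p_nh <- theta[3]; chi_nb <- theta[4]
  free_r2 <- length(theta) >= 5L
  r2_eff <- if (free_r2) theta[5] else r2
  dom <- delta_omega(hct, yv, constants)
  mf <- exp(-r2_eff * te_fid - dbv * fc_fast(dom * te_fid) - r2p_nh * te_fid)
  tau <- tr - te_echo
  me <- exp(-r2_eff * te_echo - dbv * fc_fast(dom * tau) - r2p_nh * tau)
  a_f <- sum(y_fid * mf) / sum(mf^2)
  a_e <- sum(y_echo * me) / sum(me^2)
  r <- c(y_fid - a_f * mf, y_echo - a_e * me)
  if (w > 0) {
    r <- c(r, sqrt(w) * (dchi_prior -
                           psi_raw(yv, chi_nb, cbvv_prior, cbva, hct, constants)))
  }
  if (p > 0) {
    r <- c(r, sqrt(p) * (r2p_prior - yfun_raw(yv, dbv, r2p_nh, hct, constants)))
  }
  if (free_r2 && p_r2 > 0) {
    r <- c(r, sqrt(p_r2) * (r2 - r2_eff))
  }
  if (w_dbv > 0) {
    r <- c(r, sqrt(w_dbv) * (cbvv_prior - dbv))
  }
  r
}

#' Constrained qBOLD objective for one voxel
#'
#' Value of the penalised least-squares objective (data misfit for both
#' components with amplitudes profiled out, plus the weighted
#' susceptibility- and R2'-consistency penalties) at a given parameter
#' vector. Exposed for diagnostics and objective-surface scans.
#'
#' @param theta Numeric vector `c(yv, dbv, r2p_nh, chi_nb)`, optionally with
#'   a fifth element carrying a free R2.
#' @param y_fid,y_echo Echo magnitude vectors.
#' @param priors Named list with scalars `r2`, `r2p`, `dchi`, `cbvv`.
#' @param hct Hematocrit (scalar).
#' @param acq [acquisition_config()].
#' @param w,p,p_r2 Penalty weights (numbers).
#' @param cbva Fixed arterial blood volume fraction.
#' @param constants [physics_constants()].
#' @return Scalar objective value.
#' @export
qbold_objective <- function(theta, y_fid, y_echo, priors, hct,
                            acq = acquisition_config(), w = 0, p = 0,
                            p_r2 = 0, cbva = 0.01,
                            constants = physics_constants()) {
  r <- qbold_residual(theta, y_fid, y_echo, acq$te_fid, acq$te_echo,
                      acq$ausfide_tr, priors$r2, priors$dchi, priors$r2p,
                      priors$cbvv, hct, w, p, cbva, constants, p_r2 = p_r2)
  sum(r^2)
}

qbold_init <- function(priors, hct, weights, constants) {
  b <- weights$bounds
  dbv0 <- min(max(priors$cbvv, b$dbv[1]), b$dbv[2])
  r2p_nh0 <- min(max(0.2 * priors$r2p, b$r2p_nh[1]), b$r2p_nh[2])
  kfac <- (4 * pi / 3) * constants$gamma * constants$b0 *
    (constants$delta_chi_do * 1e-6) * hct
  one_minus_yv <- max(priors$r2p - r2p_nh0, 0) / max(dbv0 * kfac, 1e-12)
  yv0 <- min(max(1 - one_minus_yv, b$yv[1]), b$yv[2])
  # chi_nb consistent with the susceptibility prior at (yv0, cbvv)
  art <- constants$chi_oxy + hct * constants$delta_chi_do * (1 - constants$sao2)
  ven <- constants$chi_oxy + hct * constants$delta_chi_do * (1 - yv0)
  denom <- 1 - weights$cbva - priors$cbvv
  chi0 <- (priors$dchi - weights$cbva * art - priors$cbvv * ven) /
    max(denom, 0.5)
  chi0 <- min(max(chi0, b$chi_nb[1]), b$chi_nb[2])
  c(yv = yv0, dbv = dbv0, r2p_nh = r2p_nh0, chi_nb = chi0)
}

#' Fit the constrained qBOLD model in one voxel
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) for the unknowns
#' `yv`, `dbv`, `r2p_nh`, `chi_nb`, minimising the stacked residual of the
#' FID and ECHO echo trains (component amplitudes profiled out by a linear
#' solve at every iterate) plus the susceptibility- and R2'-consistency
#' penalties against the measured priors. Initialization inverts the R2'
#' decomposition with DBV set to the CBVv prior; optionally a grid of Yv
#' starts is tried and the lowest objective kept (ties broken by lower DBV).
#'
#' @param y_fid,y_echo Echo magnitude vectors (>= 3 echoes each).
#' @param priors Named list with finite scalars `r2`, `r2p`, `dchi`, `cbvv`.
#' @param hct Hematocrit (scalar fraction).
#' @param acq [acquisition_config()].
#' @param weights [fit_weights()].
#' @param constants [physics_constants()].
#' @return List: `theta` (named vector), `oef`, `a_fid`, `a_echo`,
#'   `objective`, `residual_norm`, `iterations`, `converged`, `rsstrace`.
#' @export
fit_qbold_voxel <- function(y_fid, y_echo, priors, hct,
                            acq = acquisition_config(),
                            weights = fit_weights(),
                            constants = physics_constants()) {
  if (length(y_fid) < 3L || length(y_echo) < 3L) {
    abort("Need at least 3 echoes per component.")
  }
  pr <- priors
  if (!all(is.finite(c(pr$r2, pr$r2p, pr$dchi, pr$cbvv)))) {
    abort("Priors must be finite.")
  }
  if (!all(is.finite(y_fid)) || !all(is.finite(y_echo)) ||
      max(y_fid) <= 0 || max(y_echo) <= 0) {
    return(list(theta = c(yv = NA_real_, dbv = NA_real_, r2p_nh = NA_real_,
                          chi_nb = NA_real_),
                oef = NA_real_, a_fid = NA_real_, a_echo = NA_real_,
                objective = NA_real_, residual_norm = NA_real_,
                iterations = 0L, converged = FALSE, valid = FALSE))
  }

  theta0 <- qbold_init(pr, hct, weights, constants)
  b <- weights$bounds
  lower <- c(b$yv[1], b$dbv[1], b$r2p_nh[1], b$chi_nb[1])
  upper <- c(b$yv[2], b$dbv[2], b$r2p_nh[2], b$chi_nb[2])
  if (isTRUE(weights$estimate_r2)) {
    theta0 <- c(theta0, r2 = min(max(pr$r2, b$r2[1]), b$r2[2]))
    lower <- c(lower, b$r2[1])
    upper <- c(upper, b$r2[2])
  }

  if (weights$dbv_equals_cbvv) {
    dbv_pin <- min(max(pr$cbvv, b$dbv[1]), b$dbv[2])
    lower[2] <- upper[2] <- theta0[2] <- dbv_pin
    upper[2] <- upper[2] + 1e-12
  }

  # noise-adaptive auto weights: each penalty is an inverse-variance weight
  # sigma_noise^2 / sigma_prior^2, with the noise variance estimated from
  # second differences of the echo trains (white noise inflates squared
  # second differences by a factor 6; the smooth decay contributes little)
  # and sigma_prior the floor scale of each measured prior
  d2 <- c(diff(y_fid, differences = 2), diff(y_echo, differences = 2))
  sigma2 <- mean(d2^2) / 6
  resolve_w <- function(x, floor_scale) {
    if (!identical(x, "auto")) return(x)
    sigma2 / floor_scale^2
  }
  w <- resolve_w(weights$w, weights$chi_floor)
  p <- resolve_w(weights$p, weights$r2p_floor)
  p_r2 <- resolve_w(weights$p_r2, weights$r2_floor)
  w_dbv <- if (weights$dbv_equals_cbvv) 0 else
    resolve_w(weights$w_dbv, weights$dbv_floor)

  starts <- list(theta0)
  if (weights$multistart > 1L) {
    yv_grid <- seq(b$yv[1] + 0.02, b$yv[2] - 0.02,
                   length.out = weights$multistart)
    starts <- c(starts, lapply(yv_grid, function(yv) {
      th <- theta0; th[1] <- yv; th
    }))
  }

  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = th0,
        lower = lower, upper = upper,
        fn = qbold_residual,
        y_fid = y_fid, y_echo = y_echo,
        te_fid = acq$te_fid, te_echo = acq$te_echo, tr = acq$ausfide_tr,
        r2 = pr$r2, dchi_prior = pr$dchi, r2p_prior = pr$r2p,
        cbvv_prior = pr$cbvv, hct = hct, w = w, p = p, p_r2 = p_r2,
        w_dbv = w_dbv, cbva = weights$cbva, constants = constants,
        control = minpack.lm::nls.lm.control(
          maxiter = weights$max_iter, ftol = weights$ftol,
          ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    obj <- fit$deviance
    if (is.null(best) || obj < best$deviance - 1e-14 ||
        (abs(obj - best$deviance) <= 1e-14 && fit$par[2] < best$par[2])) {
      best <- fit
    }
  }
  if (is.null(best)) {
    return(list(theta = theta0, oef = NA_real_, a_fid = NA_real_,
                a_echo = NA_real_, objective = NA_real_,
                residual_norm = NA_real_, iterations = 0L,
                converged = FALSE, valid = FALSE))
  }

  th <- best$par
  names(th) <- c("yv", "dbv", "r2p_nh", "chi_nb",
                 "r2")[seq_along(th)]
  r2_hat <- if (isTRUE(weights$estimate_r2)) th[["r2"]] else pr$r2
  dom <- delta_omega(hct, th[["yv"]], constants)
  mf <- exp(-r2_hat * acq$te_fid - th[["dbv"]] * fc_fast(dom * acq$te_fid) -
              th[["r2p_nh"]] * acq$te_fid)
  tau <- acq$ausfide_tr - acq$te_echo
  me <- exp(-r2_hat * acq$te_echo - th[["dbv"]] * fc_fast(dom * tau) -
              th[["r2p_nh"]] * tau)
  list(theta = th, r2 = r2_hat,
       oef = (constants$sao2 - th[["yv"]]) / constants$sao2,
       a_fid = sum(y_fid * mf) / sum(mf^2),
       a_echo = sum(y_echo * me) / sum(me^2),
       objective = best$deviance,
       residual_norm = sqrt(best$deviance),
       iterations = best$niter,
       converged = best$info %in% 1:4,
       rsstrace = best$rsstrace,
       w = w, p = p, p_r2 = p_r2, valid = TRUE)
}

#' Fit the constrained qBOLD model over a volume
#'
#' Applies [fit_qbold_voxel()] to every voxel of the mask, assembling
#' parameter maps for venous oxygen saturation, OEF, deoxygenated blood
#' volume, non-heme R2' and non-blood susceptibility, with per-voxel fit
#' diagnostics. When the priors carry a CBF map, a CMRO2 map is computed by
#' Fick's principle using the supplied hematocrit.
#'
#' @param series An `ausfide_series`.
#' @param priors A `prior_maps` object (or compatible list of arrays).
#' @param hct Scalar hematocrit (per subject).
#' @param acq [acquisition_config()].
#' @param weights [fit_weights()].
#' @param mask Logical array (default: series mask and valid priors).
#' @param constants [physics_constants()].
#' @return A `qbold_result`: arrays `yv`, `oef`, `dbv`, `r2p_nh`, `chi_nb`,
#'   `residual_norm`, `iterations`, `converged`, optionally `cmro2`, and a
#'   `summary` list (fraction converged, median iterations).
#' @export
fit_qbold <- function(series, priors, hct, acq = acquisition_config(),
                      weights = fit_weights(), mask = NULL,
                      constants = physics_constants()) {
  stopifnot(inherits(series, "ausfide_series"))
  dims <- dim(series$fid)[1:3]
  if (!all(dim(priors$r2) == dims)) {
    abort("Prior maps and series have mismatched grids.")
  }
  if (is.null(mask)) {
    mask <- series$mask & is.finite(priors$r2) & is.finite(priors$r2p) &
      is.finite(priors$dchi_ppm) & is.finite(priors$cbvv)
  }
  idx <- which(mask)
  nv3 <- prod(dims)
  ne <- length(series$te_fid)

  new_map <- function() array(NA_real_, dims)
  out <- list(yv = new_map(), oef = new_map(), dbv = new_map(),
              r2p_nh = new_map(), chi_nb = new_map(), r2 = new_map(),
              residual_norm = new_map(), iterations = new_map(),
              converged = array(FALSE, dims))

  if (length(idx)) {
    mag_f <- matrix(0, length(idx), ne)
    mag_e <- matrix(0, length(idx), ne)
    for (k in seq_len(ne)) {
      mag_f[, k] <- abs(series$fid[idx + (k - 1L) * nv3])
      mag_e[, k] <- abs(series$echo[idx + (k - 1L) * nv3])
    }
    for (i in seq_along(idx)) {
      v <- idx[i]
      pr <- list(r2 = priors$r2[v], r2p = priors$r2p[v],
                 dchi = priors$dchi_ppm[v], cbvv = priors$cbvv[v])
      fit <- fit_qbold_voxel(mag_f[i, ], mag_e[i, ], pr, hct, acq, weights,
                             constants)
      out$yv[v] <- fit$theta[["yv"]]
      out$oef[v] <- fit$oef
      out$dbv[v] <- fit$theta[["dbv"]]
      out$r2p_nh[v] <- fit$theta[["r2p_nh"]]
      out$chi_nb[v] <- fit$theta[["chi_nb"]]
      out$r2[v] <- fit$r2 %||% pr$r2
      out$residual_norm[v] <- fit$residual_norm
      out$iterations[v] <- fit$iterations
      out$converged[v] <- isTRUE(fit$converged)
    }
  }

  nfit <- length(idx)
  out$summary <- list(
    n_voxels = nfit,
    fraction_converged = if (nfit) mean(out$converged[idx]) else NA_real_,
    median_iterations = if (nfit) median(out$iterations[idx]) else NA_real_)
  out$mask <- mask
  out$hct <- hct

  if (!is.null(priors$cbf) && any(is.finite(priors$cbf))) {
    out$cmro2 <- cmro2_map(out, priors$cbf, hct, constants)
  }
  class(out) <- "qbold_result"
  out
}

#' @export
print.qbold_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<qbold_result> %d voxels fitted, %.1f%% converged, median %d iterations\n",
              s$n_voxels, 100 * (s$fraction_converged %||% NA), s$median_iterations))
  if (s$n_voxels) {
    cat(sprintf("  OEF: median %.3f [%.3f, %.3f]\n",
                median(x$oef[x$mask], na.rm = TRUE),
                quantile(x$oef[x$mask], 0.05, na.rm = TRUE),
                quantile(x$oef[x$mask], 0.95, na.rm = TRUE)))
  }
  invisible(x)
}

#' CMRO2 map from an OEF result and a CBF map
#'
#' Voxelwise Fick's principle. Non-finite OEF or CBF propagates as NA.
#'
#' @param result A `qbold_result` (or any list with an `oef` array).
#' @param cbf CBF array, mL/100 g/min, congruent with the OEF map.
#' @param hct Scalar hematocrit in (0, 1).
#' @param constants [physics_constants()].
#' @return CMRO2 array, umol O2/100 g/min.
#' @export
cmro2_map <- function(result, cbf, hct, constants = physics_constants()) {
  if (!is.numeric(hct) || hct <= 0 || hct >= 1) {
    abort("`hct` must be a scalar in (0, 1).")
  }
  oef <- result$oef
  if (!all(dim(oef) == dim(cbf))) abort("OEF and CBF grids are mismatched.")
  # negative CBF (possible under ASL noise) is unphysical: marked invalid
  ok <- is.finite(oef) & is.finite(cbf) & cbf >= 0
  out <- array(NA_real_, dim(oef))
  out[ok] <- fick_cmro2(cbf[ok], hct, pmin(pmax(oef[ok], 0), 1), constants)
  out
}
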
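#' Fit mono-exponential decay rates from FID/ECHO magnitude data
#'
#' Weighted log-linear fits per voxel (weights = squared magnitude, the
#' standard variance-stabilising weighting for log-transformed magnitudes)
#' give the effective FID decay rate (R2 + R2') and ECHO decay rate
#' (R2 - R2'); then `R2 = (rate_FID + rate_ECHO)/2`,
#' `R2' = (rate_FID - rate_ECHO)/2`, `R2* = rate_FID`. Negative R2' values
#' are clipped to zero and flagged. Voxels with non-positive or degenerate
#' signal are marked invalid (NA), never raised as errors.
#'
#' Because the reversible dephasing is quadratic rather than linear at small
#' arguments, the echoes closest to that regime (the earliest FID echoes and
#' the latest ECHO echoes, where the reversible time `TR - TE` is shortest)
#' curve away from a mono-exponential and bias the rates low; `trim` of them
#' are excluded from each component's fit (kept when fewer than 3 echoes
#' would remain).
#'
#' @param series An `ausfide_series` from [simulate_ausfide()].
#' @param mask Logical array of voxels to fit (default: the series mask).
#' @param trim Number of most-curved echoes excluded per component.
#' @return List of arrays `r2`, `r2p`, `r2star`, plus logical `clipped` and
#'   `valid` arrays.
#' @export
fit_decay_rates <- function(series, mask = series$mask, trim = 3L) {
  stopifnot(inherits(series, "ausfide_series"))
  ne <- length(series$te_fid)
  if (ne < 3L) abort("Need at least 3 echoes per component.")
  trim <- as.integer(trim)
  if (ne - trim < 3L) trim <- max(0L, ne - 3L)
  dims <- dim(series$fid)[1:3]
  idx <- which(mask)
  nvox <- length(idx)
  nv3 <- prod(dims)

  mag_at <- function(arr, k) abs(arr[idx + (k - 1L) * nv3])
  get_mat <- function(arr) {
    m <- matrix(0, nvox, ne)
    for (k in seq_len(ne)) m[, k] <- mag_at(arr, k)
    m
  }
  mf <- get_mat(series$fid)
  me <- get_mat(series$echo)

  wfit_rate <- function(m, te) {
    nk <- ncol(m)
    ok <- m > 0
    valid <- rowSums(ok) >= 3L
    y <- log(pmax(m, .Machine$double.xmin))
    w <- m^2
    w[!ok] <- 0
    sw <- rowSums(w)
    te_mat <- matrix(te, nvox, nk, byrow = TRUE)
    tbar <- rowSums(w * te_mat) / sw
    ybar <- rowSums(w * y) / sw
    dt <- te_mat - tbar
    slope <- rowSums(w * dt * y) / rowSums(w * dt^2)
    slope[!valid] <- NA_real_
    list(rate = -slope, valid = valid)
  }
  kf <- (trim + 1L):ne      # FID: drop earliest echoes (small delta-omega*TE)
  ke <- 1L:(ne - trim)      # ECHO: drop latest echoes (small TR - TE)
  ff <- wfit_rate(mf[, kf, drop = FALSE], series$te_fid[kf])
  fe <- wfit_rate(me[, ke, drop = FALSE], series$te_echo[ke])

  to_vol <- function(v) {
    out <- array(NA_real_, dims)
    out[idx] <- v
    out
  }
  r2 <- (ff$rate + fe$rate) / 2
  r2p <- (ff$rate - fe$rate) / 2
  clipped <- !is.na(r2p) & r2p < 0
  r2p[clipped] <- 0
  r2star <- r2 + r2p

  list(r2 = to_vol(r2), r2p = to_vol(r2p), r2star = to_vol(r2star),
       clipped = to_vol(as.numeric(clipped)) > 0,
       valid = to_vol(as.numeric(ff$valid & fe$valid)) > 0)
}

#' Estimate the macroscopic field offset map from FID phase
#'
#' Temporal phase unwrapping across echoes (successive phase differences
#' wrapped into (-pi, pi], then accumulated) followed by a magnitude-weighted
#' linear fit of phase versus echo time. The slope (rad/s) is converted to
#' ppm of the main field. Voxels whose fitted phase advance per echo spacing
#' exceeds pi (beyond the unwrapping capture range) are flagged.
#'
#' @param series An `ausfide_series`.
#' @param mask Logical array (default: series mask).
#' @param constants [physics_constants()].
#' @return List with `db0_ppm` array and logical `aliased` flag array.
#' @export
estimate_fieldmap <- function(series, mask = series$mask,
                              constants = physics_constants()) {
  stopifnot(inherits(series, "ausfide_series"))
  ne <- length(series$te_fid)
  if (ne < 2L) abort("Need at least 2 FID echoes.")
  dims <- dim(series$fid)[1:3]
  idx <- which(mask)
  nvox <- length(idx)
  nv3 <- prod(dims)

  sig <- matrix(0i, nvox, ne)
  for (k in seq_len(ne)) sig[, k] <- series$fid[idx + (k - 1L) * nv3]
  mag <- abs(sig)
  phase <- matrix(0, nvox, ne)
  phase[, 1] <- Arg(sig[, 1])
  if (ne >= 2) {
    dphi <- Arg(sig[, -1, drop = FALSE] * Conj(sig[, -ne, drop = FALSE]))
    phase[, -1] <- phase[, 1] + t(apply(dphi, 1, cumsum))
  }

  te <- series$te_fid
  w <- mag^2
  sw <- rowSums(w)
  te_mat <- matrix(te, nvox, ne, byrow = TRUE)
  tbar <- rowSums(w * te_mat) / sw
  dt <- te_mat - tbar
  slope <- rowSums(w * dt * phase) / rowSums(w * dt^2)

  spacing <- if (ne > 1) te[2] - te[1] else NA_real_
  aliased <- abs(slope) * spacing > pi
  db0 <- slope / (constants$gamma * constants$b0 * 1e-6)

  out <- array(NA_real_, dims)
  out[idx] <- db0
  fl <- array(FALSE, dims)
  fl[idx] <- aliased
  list(db0_ppm = out, aliased = fl)
}

# fftfreq-style normalised frequency coordinates for one axis
fft_freq <- function(n) {
  i <- seq_len(n) - 1L
  ifelse(i <= n %/% 2, i, i - n) / n
}

dipole_kernel <- function(dims, voxel_size = c(1, 1, 1)) {
  kx <- fft_freq(dims[1]) / voxel_size[1]
  ky <- fft_freq(dims[2]) / voxel_size[2]
  kz <- fft_freq(dims[3]) / voxel_size[3]
  KX2 <- array(rep(kx^2, times = dims[2] * dims[3]), dims)
  KY2 <- array(rep(rep(ky^2, each = dims[1]), times = dims[3]), dims)
  KZ2 <- array(rep(kz^2, each = dims[1] * dims[2]), dims)
  k2 <- KX2 + KY2 + KZ2
  d <- 1 / 3 - KZ2 / k2
  d[k2 == 0] <- 0
  d
}

#' Forward dipole convolution of a susceptibility distribution
#'
#' Computes the field perturbation (same units as `chi`, e.g. ppm) generated
#' by a susceptibility distribution via the k-space unit dipole kernel
#' `D(k) = 1/3 - kz^2/|k|^2` (k = 0 term set to 0). Serves as the forward
#' model whose Tikhonov-regularised inverse is [invert_dipole()].
#'
#' @param chi 3-D susceptibility array (ppm).
#' @param voxel_size Voxel size (mm), affects only anisotropic grids.
#' @return Field array, same dimensions.
#' @export
dipole_field <- function(chi, voxel_size = c(1, 1, 1)) {
  dims <- dim(chi)
  d <- dipole_kernel(dims, voxel_size)
  Re(fft(d * fft(chi), inverse = TRUE)) / prod(dims)
}

#' Tikhonov-regularised dipole inversion (QSM)
#'
#' Recovers a relative susceptibility map from a field map: a low-order
#' polynomial background field is removed within the mask, then the k-space
#' inverse filter `conj(D) / (|D|^2 + reg)` is applied with the unit dipole
#' kernel `D(k) = 1/3 - kz^2/|k|^2`.
#'
#' @param field_ppm 3-D field map (ppm).
#' @param mask Logical array of valid voxels.
#' @param reg Tikhonov regularisation parameter (> 0).
#' @param detrend_order Polynomial order of the background removal (0 skips).
#' @param voxel_size Voxel size (mm).
#' @return List with the susceptibility array `dchi_ppm` (NA outside mask)
#'   and the removed `background` field.
#' @export
invert_dipole <- function(field_ppm, mask = NULL, reg = 1e-2,
                          detrend_order = 2, voxel_size = c(1, 1, 1)) {
  if (!is.numeric(reg) || reg <= 0) abort("`reg` must be > 0.")
  dims <- dim(field_ppm)
  if (is.null(mask)) mask <- array(TRUE, dims)
  f <- field_ppm
  f[!mask] <- 0
  f[is.na(f)] <- 0

  background <- array(0, dims)
  if (detrend_order > 0 && sum(mask) > 20) {
    cx <- (seq_len(dims[1]) - (dims[1] + 1) / 2) / (dims[1] / 2)
    cy <- (seq_len(dims[2]) - (dims[2] + 1) / 2) / (dims[2] / 2)
    cz <- (seq_len(dims[3]) - (dims[3] + 1) / 2) / (dims[3] / 2)
    X <- array(rep(cx, times = dims[2] * dims[3]), dims)
    Y <- array(rep(rep(cy, each = dims[1]), times = dims[3]), dims)
    Z <- array(rep(cz, each = dims[1] * dims[2]), dims)
    terms <- list(rep(1, prod(dims)), X, Y, Z)
    if (detrend_order >= 2) {
      terms <- c(terms, list(X^2, Y^2, Z^2, X * Y, X * Z, Y * Z))
    }
    design <- do.call(cbind, lapply(terms, as.vector))
    beta <- stats::lm.fit(design[mask, , drop = FALSE], f[mask])$coefficients
    beta[is.na(beta)] <- 0
    background <- array(design %*% beta, dims)
    f <- f - background
    f[!mask] <- 0
  }

  d <- dipole_kernel(dims, voxel_size)
  chi <- Re(fft(Conj(d) * fft(f) / (d^2 + reg), inverse = TRUE)) / prod(dims)
  chi[!mask] <- NA_real_
  list(dchi_ppm = chi, background = background)
}

#' Quantify venous cerebral blood volume from a VS-VSL pair
#'
#' `CBVv = (control - tag) / (2 * kappa * m0b)` with
#' `kappa = exp(-TI / T1b)`. Negative values are clipped to zero and flagged.
#'
#' @param pair A `vsvsl_pair` (or any list with `control` and `tag` arrays).
#' @param acq [acquisition_config()] supplying TI and blood T1.
#' @param m0b Equilibrium venous blood signal scale (> 0).
#' @return List with `cbvv` array and logical `clipped` array.
#' @export
quantify_cbvv <- function(pair, acq = acquisition_config(), m0b = 100) {
  if (!is.numeric(m0b) || m0b <= 0) abort("`m0b` must be positive.")
  if (!all(dim(pair$control) == dim(pair$tag))) {
    abort("Control and tag volumes must be congruent.")
  }
  kappa <- exp(-acq$vsvl_ti / acq$blood_t1)
  cbvv <- (pair$control - pair$tag) / (2 * kappa * m0b)
  clipped <- !is.na(cbvv) & cbvv < 0
  cbvv[clipped] <- 0
  list(cbvv = cbvv, clipped = clipped)
}

#' Quantify CBF from pCASL control/label pairs
#'
#' Consensus single-compartment quantification:
#' \deqn{\mathrm{CBF} = \frac{6000\,\lambda\,\Delta M\,
#'   e^{\mathrm{PLD}/T_{1b}}}{2\,\alpha\,T_{1b}\,
#'   (1 - e^{-\tau/T_{1b}})\,M_0}}
#' in mL/100 g/min, with \eqn{\Delta M} the mean control-label difference.
#' Voxels with non-positive M0 are flagged invalid (NA).
#'
#' @param series A `pcasl_series` (lists `control`, `label`, array `m0`).
#' @param m0 M0 volume override (default: `series$m0`).
#' @param acq [acquisition_config()] supplying lambda, T1b, alpha, tau, PLD.
#' @return List with `cbf` array and logical `invalid` array.
#' @export
quantify_cbf <- function(series, m0 = series$m0, acq = acquisition_config()) {
  np <- length(series$control)
  if (np < 1L) abort("Need at least one control/label pair.")
  dm <- Reduce(`+`, Map(`-`, series$control, series$label)) / np
  lam <- acq$partition_coefficient
  t1b <- acq$blood_t1
  alpha <- acq$labeling_efficiency
  tau <- acq$pcasl_label_duration
  pld <- acq$pcasl_pld
  invalid <- !(m0 > 0) | is.na(m0)
  cbf <- 6000 * lam * dm * exp(pld / t1b) /
    (2 * alpha * t1b * (1 - exp(-tau / t1b)) * m0)
  cbf[invalid] <- NA_real_
  list(cbf = cbf, invalid = invalid)
}

#' Estimate the full set of prior constraint maps
#'
#' Convenience wrapper running [fit_decay_rates()], [estimate_fieldmap()],
#' [invert_dipole()], [quantify_cbvv()], and [quantify_cbf()] to produce the
#' measured constraints fed to the voxelwise constrained inversion: R2, R2',
#' R2*, the field offset, the relative susceptibility, venous CBV, and CBF.
#'
#' @param ausfide An `ausfide_series`.
#' @param vsvsl A `vsvsl_pair` (optional; CBVv map NA if absent).
#' @param pcasl A `pcasl_series` (optional; CBF map NA if absent).
#' @param mask Logical array.
#' @param acq [acquisition_config()].
#' @param m0b VS-VSL blood signal scale.
#' @param reg Dipole-inversion regularisation.
#' @param constants [physics_constants()].
#' @return A `prior_maps` list of arrays: `r2`, `r2p`, `r2star`, `db0_ppm`,
#'   `dchi_ppm`, `cbvv`, `cbf`, plus flag arrays.
#' @export
fit_prior_maps <- function(ausfide, vsvsl = NULL, pcasl = NULL,
                           mask = ausfide$mask, acq = acquisition_config(),
                           m0b = 100, reg = 1e-2,
                           constants = physics_constants()) {
  rates <- fit_decay_rates(ausfide, mask)
  fmap <- estimate_fieldmap(ausfide, mask, constants)
  qsm <- invert_dipole(fmap$db0_ppm, mask, reg = reg,
                       voxel_size = ausfide$voxel_size %||% c(1, 1, 1))
  dims <- dim(rates$r2)
  cbvv <- array(NA_real_, dims)
  if (!is.null(vsvsl)) cbvv <- quantify_cbvv(vsvsl, acq, m0b)$cbvv
  cbf <- array(NA_real_, dims)
  if (!is.null(pcasl)) cbf <- quantify_cbf(pcasl, acq = acq)$cbf
  structure(
    list(r2 = rates$r2, r2p = rates$r2p, r2star = rates$r2star,
         db0_ppm = fmap$db0_ppm, dchi_ppm = qsm$dchi_ppm,
         cbvv = cbvv, cbf = cbf,
         clipped = rates$clipped, valid = rates$valid,
         aliased = fmap$aliased, mask = mask),
    class = "prior_maps"
  )
}
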
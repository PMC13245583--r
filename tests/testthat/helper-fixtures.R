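# shared fixtures built in code

# two-region (GM shell + WM core) phantom with flat background field
tiny_phantom <- function(dim = c(8, 8, 8), yv = NULL, dbv = NULL, r2 = NULL,
                         r2p_nh = NULL, cbvv = NULL, chi_nb = NULL,
                         db0 = 0) {
  rp <- default_region_params()[1:2, ]
  if (!is.null(yv)) rp$yv <- yv
  if (!is.null(dbv)) rp$dbv <- dbv
  if (!is.null(r2)) rp$r2 <- r2
  if (!is.null(r2p_nh)) rp$r2p_nh <- r2p_nh
  if (!is.null(cbvv)) rp$cbvv <- cbvv
  if (!is.null(chi_nb)) rp$chi_nb <- chi_nb
  make_digital_phantom(dim = dim, region_params = rp,
                       db0_amplitude_ppm = db0)
}

# noiseless echo magnitudes for one voxel straight from the closed form
voxel_magnitudes <- function(yv, dbv, r2, r2p_nh, hct = 0.44,
                             acq = acquisition_config(),
                             a_fid = 100, a_echo = 80) {
  dom <- delta_omega(hct, yv)
  fid <- a_fid * exp(-r2 * acq$te_fid -
                       dbv * static_dephasing_fc(dom * acq$te_fid, "spline") -
                       r2p_nh * acq$te_fid)
  tau <- acq$ausfide_tr - acq$te_echo
  echo <- a_echo * exp(-r2 * acq$te_echo -
                         dbv * static_dephasing_fc(dom * tau, "spline") -
                         r2p_nh * tau)
  list(fid = fid, echo = echo)
}

# self-consistent priors for such a voxel
voxel_priors <- function(yv, dbv, r2, r2p_nh, cbvv = dbv, chi_nb = 0.01,
                         hct = 0.44, cbva = 0.01,
                         constants = physics_constants()) {
  st <- voxel_state(yv = yv, dbv = dbv, r2 = r2, r2p_nh = r2p_nh,
                    chi_nb = chi_nb, cbvv = cbvv, cbva = cbva, hct = hct)
  list(r2 = r2, r2p = r2prime_model(st, constants),
       dchi = susceptibility_model(st, constants), cbvv = cbvv)
}

# ordinary least-squares log-slope, the finite-difference oracle for rates
log_slope <- function(mag, te) {
  unname(coef(lm(log(mag) ~ te))[2])
}
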
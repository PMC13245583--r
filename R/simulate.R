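#' Simulate the multi-echo SSFP FID/ECHO acquisition
#'
#' Generates complex FID and ECHO echo stacks on the phantom grid from the
#' closed-form qBOLD forward model: the FID component decays with effective
#' rate R2 + R2' and the ECHO component with R2 - R2' (linear regime), with
#' the full static-dephasing function governing the reversible part.
#' Macroscopic field offsets accrue phase as `2*pi*gammabar*dB0*TE` on the
#' FID echoes (refocused-phase convention on the ECHO). Additive
#' circularly-symmetric complex Gaussian noise with per-channel (real /
#' imaginary) standard deviation `noise_sd` is applied when requested.
#'
#' @param truth A [make_digital_phantom()] result.
#' @param acq [acquisition_config()].
#' @param noise_sd Per-channel noise SD in signal units (>= 0).
#' @param seed Integer seed for the noise draw (deterministic output).
#' @param a_fid,a_echo Component amplitudes (signal units).
#' @param include_susceptibility_field If `TRUE` (default), the voxel
#'   susceptibility distribution (four-pool model evaluated on the truth
#'   maps) is forward-convolved with the dipole kernel and added to the
#'   smooth background field, so that phase processing (field mapping +
#'   dipole inversion) can recover the susceptibility priors.
#' @param constants [physics_constants()].
#' @return An `ausfide_series`: complex arrays `fid` and `echo` of dimension
#'   `c(dim(truth), n_echoes)`, echo-time vectors, `tr`, and the mask used.
#' @examples
#' ph <- make_digital_phantom(dim = c(8, 8, 8),
#'   region_params = default_region_params()[1:2, ])
#' ser <- simulate_ausfide(ph, noise_sd = 0)
#' dim(ser$fid)
#' @export
simulate_ausfide <- function(truth, acq = acquisition_config(), noise_sd = 0,
                             seed = NULL, a_fid = 100, a_echo = 80,
                             include_susceptibility_field = TRUE,
                             constants = physics_constants()) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    abort("`noise_sd` must be a nonnegative number.")
  }
  mask <- truth$labels > 0L
  idx <- which(mask)
  ne <- acq$ausfide_n_echoes
  dims <- c(truth$dim, ne)
  fid <- array(complex(real = 0), dims)
  echo <- array(complex(real = 0), dims)

  field_ppm <- truth$db0_ppm
  if (include_susceptibility_field) {
    psi <- phantom_susceptibility(truth, constants)
    psi[is.na(psi)] <- 0
    field_ppm <- field_ppm + dipole_field(psi, truth$voxel_size)
  }

  dom <- delta_omega(truth$hct, truth$maps$yv[idx], constants)
  r2 <- truth$maps$r2[idx]
  dbv <- truth$maps$dbv[idx]
  r2p_nh <- truth$maps$r2p_nh[idx]
  db0 <- field_ppm[idx]
  dphi_rate <- constants$gamma * constants$b0 * db0 * 1e-6
  nvox <- length(idx)

  for (k in seq_len(ne)) {
    te_f <- acq$te_fid[k]
    te_e <- acq$te_echo[k]
    mag_f <- a_fid * exp(-r2 * te_f - dbv * fc_fast(dom * te_f) - r2p_nh * te_f)
    tau_e <- acq$ausfide_tr - te_e
    mag_e <- a_echo * exp(-r2 * te_e - dbv * fc_fast(dom * tau_e) - r2p_nh * tau_e)
    fid[idx + (k - 1L) * prod(truth$dim)] <- mag_f * exp(1i * dphi_rate * te_f)
    echo[idx + (k - 1L) * prod(truth$dim)] <- mag_e * exp(-1i * dphi_rate * tau_e)
  }

  if (noise_sd > 0) {
    add_noise <- function() {
      n <- prod(dims)
      fid <<- fid + complex(real = rnorm(n, 0, noise_sd),
                            imaginary = rnorm(n, 0, noise_sd))
      echo <<- echo + complex(real = rnorm(n, 0, noise_sd),
                              imaginary = rnorm(n, 0, noise_sd))
    }
    if (is.null(seed)) add_noise() else withr::with_seed(seed, add_noise())
  }

  structure(
    list(fid = fid, echo = echo, te_fid = acq$te_fid, te_echo = acq$te_echo,
         tr = acq$ausfide_tr, mask = mask, noise_sd = noise_sd,
         field_ppm = field_ppm, voxel_size = truth$voxel_size),
    class = "ausfide_series"
  )
}

#' Ground-truth voxel susceptibility of a phantom
#'
#' Evaluates the four-pool susceptibility model on the phantom truth maps
#' (arterial blood, venous blood, oxygenated-blood baseline, non-blood
#' tissue).
#'
#' @param truth A `phantom_truth`.
#' @param constants [physics_constants()].
#' @return Susceptibility array in ppm (NA outside tissue).
#' @export
phantom_susceptibility <- function(truth, constants = physics_constants()) {
  stopifnot(inherits(truth, "phantom_truth"))
  m <- truth$maps
  art <- constants$chi_oxy + truth$hct * constants$delta_chi_do * (1 - constants$sao2)
  ven <- constants$chi_oxy + truth$hct * constants$delta_chi_do * (1 - m$yv)
  m$cbva * art + m$cbvv * ven + (1 - m$cbva - m$cbvv) * m$chi_nb
}

#' Simulate a velocity-selective venous spin labeling pair
#'
#' Control and tag volumes whose difference isolates the venous blood signal:
#' `control - tag = 2 * kappa * m0b * CBVv` per voxel before noise, with
#' `kappa = exp(-TI / T1b)`. Static tissue is identical in both volumes.
#'
#' @param truth A `phantom_truth` with a `cbvv` map.
#' @param acq [acquisition_config()] supplying `vsvl_ti` and `blood_t1`.
#' @param noise_sd Additive Gaussian noise SD per volume (>= 0).
#' @param seed Integer seed for the noise draw.
#' @param m0b Equilibrium venous blood signal scale.
#' @param m0_tissue Static tissue signal level.
#' @return A `vsvsl_pair` with `control`, `tag` arrays and the `kappa` used.
#' @export
simulate_vsvsl <- function(truth, acq = acquisition_config(), noise_sd = 0,
                           seed = NULL, m0b = 100, m0_tissue = 100) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (noise_sd < 0) abort("`noise_sd` must be nonnegative.")
  mask <- truth$labels > 0L
  kappa <- exp(-acq$vsvl_ti / acq$blood_t1)
  cbvv <- ifelse(is.na(truth$maps$cbvv), 0, truth$maps$cbvv)
  static <- ifelse(mask, m0_tissue, 0)
  venous <- kappa * m0b * cbvv
  control <- static + venous
  tag <- static - venous
  if (noise_sd > 0) {
    draw <- function() {
      n <- length(control)
      control <<- control + rnorm(n, 0, noise_sd)
      tag <<- tag + rnorm(n, 0, noise_sd)
    }
    if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  }
  structure(list(control = control, tag = tag, kappa = kappa, m0b = m0b,
                 mask = mask), class = "vsvsl_pair")
}

#' Simulate a pCASL control/label series
#'
#' Generates control/label pairs whose mean difference, fed to
#' [quantify_cbf()] with the same constants, returns the ground-truth CBF
#' exactly: the per-pair difference is obtained by inverting the consensus
#' single-compartment quantification formula at the configured lambda, T1b,
#' alpha, tau and PLD.
#'
#' @param truth A `phantom_truth` with a `cbf` map.
#' @param acq [acquisition_config()].
#' @param noise_sd Additive Gaussian noise SD per volume (>= 0).
#' @param seed Integer seed.
#' @param m0 Equilibrium tissue signal level for the M0 volume.
#' @return A `pcasl_series`: lists `control` and `label` of `n_pairs` arrays,
#'   plus the `m0` volume.
#' @export
simulate_pcasl <- function(truth, acq = acquisition_config(), noise_sd = 0,
                           seed = NULL, m0 = 100) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (noise_sd < 0) abort("`noise_sd` must be nonnegative.")
  mask <- truth$labels > 0L
  cbf <- ifelse(is.na(truth$maps$cbf), 0, truth$maps$cbf)
  m0_vol <- ifelse(mask, m0, 0)
  lam <- acq$partition_coefficient
  t1b <- acq$blood_t1
  alpha <- acq$labeling_efficiency
  tau <- acq$pcasl_label_duration
  pld <- acq$pcasl_pld
  # invert: CBF = 6000 * lam * dM * exp(PLD/T1b) / (2 alpha T1b (1-exp(-tau/T1b)) M0)
  dm <- cbf * 2 * alpha * t1b * (1 - exp(-tau / t1b)) * m0_vol /
    (6000 * lam * exp(pld / t1b))
  base <- m0_vol
  control <- replicate(acq$pcasl_n_pairs, base + dm / 2, simplify = FALSE)
  label <- replicate(acq$pcasl_n_pairs, base - dm / 2, simplify = FALSE)
  if (noise_sd > 0) {
    draw <- function() {
      for (k in seq_along(control)) {
        control[[k]] <<- control[[k]] + rnorm(length(base), 0, noise_sd)
        label[[k]] <<- label[[k]] + rnorm(length(base), 0, noise_sd)
      }
    }
    if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  }
  structure(list(control = control, label = label, m0 = m0_vol, mask = mask),
            class = "pcasl_series")
}
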
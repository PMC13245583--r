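#' Physical constants for qBOLD oximetry
#'
#' Bundles the physical and physiological constants entering the qBOLD signal
#' model, the voxel susceptibility model, and Fick's principle. Defaults are
#' the values conventionally used in brain MRI oximetry at 3 T.
#'
#' @param gamma Proton gyromagnetic ratio, rad/s/T.
#' @param delta_chi_do Susceptibility difference between fully deoxygenated and
#'   fully oxygenated erythrocytes per unit hematocrit, ppm (used with the
#'   4*pi/3 sphere prefactor inside [delta_omega()]).
#' @param chi_oxy Susceptibility of fully oxygenated blood relative to water,
#'   ppm.
#' @param c_rbc Oxygen binding capacity of red blood cells, umol O2/mL.
#' @param sao2 Arterial oxygen saturation, fraction.
#' @param brain_density Brain tissue density, g/mL.
#' @param b0 Main field strength, tesla.
#'
#' @return An object of class `qbold_constants` (named list).
#' @examples
#' physics_constants()
#' physics_constants(b0 = 7)$b0
#' @export
physics_constants <- function(gamma = 2.67513e8,
                              delta_chi_do = 0.27,
                              chi_oxy = -0.03,
                              c_rbc = 19.93,
                              sao2 = 0.98,
                              brain_density = 1.05,
                              b0 = 3.0) {
  stopifnot(gamma > 0, delta_chi_do > 0, c_rbc > 0,
            sao2 > 0, sao2 <= 1, brain_density > 0, b0 > 0)
  structure(
    list(gamma = gamma, delta_chi_do = delta_chi_do, chi_oxy = chi_oxy,
         c_rbc = c_rbc, sao2 = sao2, brain_density = brain_density, b0 = b0),
    class = "qbold_constants"
  )
}

#' @export
print.qbold_constants <- function(x, ...) {
  cat("<qbold_constants>\n")
  for (nm in names(x)) cat(sprintf("  %-14s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Static dephasing signal decay function
#'
#' The dimensionless decay function of the static dephasing regime for a
#' random network of cylindrical vessels,
#' \deqn{f_c(x) = \frac{1}{3}\int_0^1 (2+u)\sqrt{1-u}\,
#'   \frac{1 - J_0(1.5\,x\,u)}{u^2}\, du,}
#' where \eqn{J_0} is the zeroth-order Bessel function and
#' \eqn{x = \delta\omega \cdot t}. The extravascular signal attenuation of a
#' voxel with deoxygenated blood volume fraction DBV is
#' \eqn{\exp(-\mathrm{DBV} \cdot f_c(\delta\omega t))}. For short times
#' \eqn{f_c(x) \approx 0.3 x^2} (quadratic, refocusable regime); for long
#' times it grows with unit slope so that the effective relaxation rate
#' contribution is \eqn{\mathrm{DBV}\cdot\delta\omega}.
#'
#' @param x Nonnegative dimensionless argument (vectorised).
#' @param method `"quadrature"` evaluates the integral by adaptive quadrature;
#'   `"spline"` uses a cached high-resolution interpolation table (identical to
#'   quadrature to ~1e-8, much faster; this is what the simulator and fitter
#'   use internally).
#'
#' @return Numeric vector, `fc(x) >= 0`, monotone nondecreasing.
#' @examples
#' static_dephasing_fc(c(0, 0.5, 5))
#' @export
static_dephasing_fc <- function(x, method = c("quadrature", "spline")) {
  method <- match.arg(method)
  if (any(!is.finite(x)) || any(x < 0)) {
    abort("`x` must be finite and nonnegative.")
  }
  if (method == "spline") return(fc_fast(x))
  vapply(x, fc_quad_1, numeric(1))
}

fc_quad_1 <- function(x) {
  if (x == 0) return(0)
  f <- function(u) {
    out <- (2 + u) * sqrt(pmax(1 - u, 0)) * (1 - besselJ(1.5 * x * u, 0)) / u^2
    # remove the 0/0 at u = 0 (limit is 0.5 * (1.5 x)^2 * 2 / 4 finite)
    out[u == 0] <- 2 * (1.5 * x)^2 / 4
    out
  }
  integrate(f, 0, 1, rel.tol = 1e-10, subdivisions = 500L)$value / 3
}

# cached spline over [0, 80]; linear extension beyond (asymptotic unit slope)
fc_fast <- function(x) {
  tab <- .oxibold_env$fc_spline
  if (is.null(tab)) {
    grid <- c(seq(0, 2, by = 0.02), seq(2.05, 10, by = 0.05), seq(10.1, 80, by = 0.1))
    vals <- vapply(grid, fc_quad_1, numeric(1))
    sf <- splinefun(grid, vals, method = "hyman")
    slope_end <- (vals[length(vals)] - vals[length(vals) - 1L]) / 0.1
    tab <- list(sf = sf, xmax = 80, ymax = vals[length(vals)], slope = slope_end)
    .oxibold_env$fc_spline <- tab
  }
  out <- numeric(length(x))
  inside <- x <= tab$xmax
  out[inside] <- tab$sf(x[inside])
  out[!inside] <- tab$ymax + tab$slope * (x[!inside] - tab$xmax)
  out
}

#' Characteristic dephasing frequency of venous blood
#'
#' Frequency offset at the surface of a vessel containing partially
#' deoxygenated blood,
#' \deqn{\delta\omega = \tfrac{4\pi}{3}\,\gamma B_0\,
#'   \Delta\chi_{do}\,\mathrm{Hct}\,(1 - Y_v),}
#' with \eqn{\Delta\chi_{do}} in ppm (applied as ppm * 1e-6).
#'
#' @param hct Hematocrit, fraction in \[0, 1\] (vectorised).
#' @param yv Venous oxygen saturation, fraction in \[0, 1\] (vectorised).
#' @param constants A [physics_constants()] object.
#' @return Characteristic frequency, rad/s.
#' @examples
#' delta_omega(0.44, 0.60) # ~160 rad/s at 3 T
#' @export
delta_omega <- function(hct, yv, constants = physics_constants()) {
  if (any(hct < 0 | hct > 1, na.rm = TRUE) || any(yv < 0 | yv > 1, na.rm = TRUE)) {
    abort("`hct` and `yv` must lie in [0, 1].")
  }
  (4 * pi / 3) * constants$gamma * constants$b0 *
    (constants$delta_chi_do * 1e-6) * hct * (1 - yv)
}

#' Voxel state for the qBOLD forward model
#'
#' Collects the per-voxel physiological parameters entering the forward signal
#' model: the four unknowns of the constrained inversion (`yv`, `dbv`,
#' `r2p_nh`, `chi_nb`) together with the fixed quantities (relaxation rate
#' `r2`, blood volumes, hematocrit, component amplitudes).
#'
#' @param yv Venous oxygen saturation (fraction).
#' @param dbv Deoxygenated blood volume fraction.
#' @param r2 Irreversible transverse relaxation rate, 1/s.
#' @param r2p_nh Non-heme contribution to the reversible rate R2', 1/s.
#' @param chi_nb Non-blood tissue susceptibility, ppm.
#' @param cbvv,cbva Venous / arterial cerebral blood volume fractions.
#' @param hct Hematocrit (fraction).
#' @param a_fid,a_echo Steady-state amplitudes of the FID and ECHO components
#'   (arbitrary signal units; treated as free scales).
#' @return A `voxel_state` list.
#' @export
voxel_state <- function(yv = 0.6, dbv = 0.03, r2 = 20, r2p_nh = 1,
                        chi_nb = 0.02, cbvv = 0.03, cbva = 0.01,
                        hct = 0.44, a_fid = 100, a_echo = 80) {
  stopifnot(yv >= 0, yv <= 1, dbv >= 0, dbv <= 0.2,
            cbvv >= 0, cbvv <= 0.2, cbva >= 0, cbva <= 0.2,
            r2 >= 0, r2p_nh >= 0, hct >= 0, hct <= 1)
  structure(list(yv = yv, dbv = dbv, r2 = r2, r2p_nh = r2p_nh,
                 chi_nb = chi_nb, cbvv = cbvv, cbva = cbva, hct = hct,
                 a_fid = a_fid, a_echo = a_echo),
            class = "voxel_state")
}

# Vectorised magnitude kernel shared by the simulator and the fitter.
# FID:  A * exp(-r2*te - dbv*fc(domega*te)      - r2p_nh*te)
# ECHO: A * exp(-r2*te - dbv*fc(domega*(tr-te)) - r2p_nh*(tr-te))
ausfide_magnitude <- function(component, te, tr, a, r2, dbv, domega, r2p_nh) {
  if (component == "fid") {
    tau <- te
  } else {
    tau <- tr - te
  }
  a * exp(-r2 * te - dbv * fc_fast(abs(domega) * tau) - r2p_nh * tau)
}

#' qBOLD forward signal for one voxel
#'
#' Complex steady-state signal of the alternating unbalanced SSFP acquisition
#' at echo time `te`. The FID component decays with effective rate
#' \eqn{R_2 + R_2'} and the ECHO component with \eqn{R_2 - R_2'} (in the
#' linear regime of the static-dephasing function), where
#' \eqn{R_2' = \mathrm{DBV}\,\delta\omega + R_2'_{nh}}. The ECHO reversible
#' dephasing is referenced to `tr - te`. Macroscopic field offsets appear as a
#' linear phase on the FID component and a refocused phase on the ECHO
#' component.
#'
#' @param state A [voxel_state()].
#' @param acq An [acquisition_config()].
#' @param component `"fid"` or `"echo"`.
#' @param te Echo time(s), seconds. For the ECHO component `te < tr` required.
#' @param db0_ppm Macroscopic field offset, ppm (default 0).
#' @param constants [physics_constants()].
#' @return Complex signal vector, one value per `te`.
#' @examples
#' st <- voxel_state()
#' Mod(qbold_signal(st, acquisition_config(), "fid", te = c(0.002, 0.01)))
#' @export
qbold_signal <- function(state, acq = acquisition_config(),
                         component = c("fid", "echo"), te,
                         db0_ppm = 0, constants = physics_constants()) {
  component <- match.arg(component)
  stopifnot(inherits(state, "voxel_state"), te >= 0)
  tr <- acq$ausfide_tr
  if (component == "echo" && any(te >= tr)) {
    abort("ECHO echo times must be strictly less than the repetition time.")
  }
  dom <- delta_omega(state$hct, state$yv, constants)
  a <- if (component == "fid") state$a_fid else state$a_echo
  mag <- ausfide_magnitude(component, te, tr, a,
                           state$r2, state$dbv, dom, state$r2p_nh)
  # phase from macroscopic field offset: accrues with te on the FID,
  # refocused (tr - te) convention on the ECHO
  dphi_rate <- constants$gamma * constants$b0 * db0_ppm * 1e-6
  phase <- if (component == "fid") dphi_rate * te else -dphi_rate * (tr - te)
  mag * exp(1i * phase)
}

#' Voxel susceptibility model (four pools)
#'
#' Volume-weighted susceptibility of a voxel decomposed into arterial blood,
#' venous blood, and non-blood tissue pools; each blood pool carries the
#' fully-oxygenated baseline plus a deoxyhemoglobin contribution:
#' \deqn{\Psi = \mathrm{CBV}_a [\chi_{oxy} + \mathrm{Hct}\,\Delta\chi_{do}
#'   (1 - S_aO_2)] + \mathrm{CBV}_v [\chi_{oxy} + \mathrm{Hct}\,
#'   \Delta\chi_{do} (1 - Y_v)] + (1 - \mathrm{CBV}_a - \mathrm{CBV}_v)\,
#'   \chi_{nb}.}
#'
#' @inheritParams qbold_signal
#' @return Susceptibility in ppm.
#' @export
susceptibility_model <- function(state, constants = physics_constants()) {
  stopifnot(inherits(state, "voxel_state"))
  if (state$cbva + state$cbvv > 1) {
    abort("Blood volume fractions sum to more than 1.")
  }
  dchi_do <- constants$delta_chi_do
  art <- constants$chi_oxy + state$hct * dchi_do * (1 - constants$sao2)
  ven <- constants$chi_oxy + state$hct * dchi_do * (1 - state$yv)
  state$cbva * art + state$cbvv * ven +
    (1 - state$cbva - state$cbvv) * state$chi_nb
}

#' Decomposition of R2' into heme and non-heme contributions
#'
#' \deqn{Y(\Theta) = \mathrm{DBV}\,\delta\omega(\mathrm{Hct}, Y_v) + R_2'_{nh}.}
#'
#' @inheritParams qbold_signal
#' @return Reversible relaxation rate R2', 1/s.
#' @export
r2prime_model <- function(state, constants = physics_constants()) {
  stopifnot(inherits(state, "voxel_state"))
  state$dbv * delta_omega(state$hct, state$yv, constants) + state$r2p_nh
}

#' CMRO2 by Fick's principle
#'
#' \deqn{\mathrm{CMRO}_2 = \mathrm{CBF} \cdot C_a \cdot S_aO_2 \cdot
#'   \mathrm{OEF},\qquad C_a = \mathrm{Hct}\cdot C_{rbc},}
#' with CBF in mL/100 g/min, the arterial oxygen carrying capacity
#' \eqn{C_a} in umol O2/mL, and CMRO2 in umol O2/100 g/min.
#'
#' @param cbf Cerebral blood flow, mL/100 g/min (vectorised).
#' @param hct Hematocrit, fraction.
#' @param oef Oxygen extraction fraction, fraction in \[0, 1\].
#' @param constants [physics_constants()].
#' @return CMRO2 in umol O2/100 g/min.
#' @examples
#' fick_cmro2(50, 0.44, 0.35) # ~150 umol/100 g/min
#' @export
fick_cmro2 <- function(cbf, hct, oef, constants = physics_constants()) {
  if (any(cbf < 0, na.rm = TRUE) || any(hct < 0, na.rm = TRUE) ||
      any(oef < 0 | oef > 1, na.rm = TRUE)) {
    abort("`cbf`, `hct` must be >= 0 and `oef` in [0, 1].")
  }
  cbf * (hct * constants$c_rbc) * constants$sao2 * oef
}

#' Convert venous oxygen saturation to oxygen extraction fraction
#'
#' OEF = (SaO2 - Yv) / SaO2, the arteriovenous saturation difference as a
#' fraction of arterial saturation. Values of `yv` above SaO2 (possible under
#' noise) are clipped to OEF = 0 with a warning attribute.
#'
#' @param yv Venous oxygen saturation (fraction, vectorised).
#' @param constants [physics_constants()].
#' @return OEF as a fraction; attribute `clipped` counts clipped entries.
#' @examples
#' oef_from_yv(0.588) # 0.40
#' @export
oef_from_yv <- function(yv, constants = physics_constants()) {
  if (any(yv < 0, na.rm = TRUE)) abort("`yv` must be nonnegative.")
  n_clip <- sum(yv > constants$sao2, na.rm = TRUE)
  if (n_clip > 0) {
    warn(sprintf("%d value(s) of yv exceed SaO2; OEF clipped to 0.", n_clip))
  }
  oef <- pmax((constants$sao2 - yv) / constants$sao2, 0)
  attr(oef, "clipped") <- n_clip
  oef
}

#' Convert oxygen extraction fraction to venous oxygen saturation
#'
#' Inverse of [oef_from_yv()]: Yv = SaO2 * (1 - OEF).
#'
#' @param oef OEF as a fraction.
#' @param constants [physics_constants()].
#' @return Venous saturation, fraction.
#' @export
yv_from_oef <- function(oef, constants = physics_constants()) {
  stopifnot(all(oef >= 0 & oef <= 1, na.rm = TRUE))
  constants$sao2 * (1 - oef)
}
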
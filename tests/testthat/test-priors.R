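# build an ausfide_series object from pure exponential components
pure_exp_series <- function(rate_fid, rate_echo, dim = c(4, 4, 4),
                            acq = acquisition_config()) {
  nv <- prod(dim)
  ne <- acq$ausfide_n_echoes
  fid <- array(complex(real = 0), c(dim, ne))
  echo <- array(complex(real = 0), c(dim, ne))
  for (k in seq_len(ne)) {
    fid[, , , k] <- 100 * exp(-rate_fid * acq$te_fid[k])
    echo[, , , k] <- 80 * exp(-rate_echo * acq$te_echo[k])
  }
  structure(list(fid = fid, echo = echo, te_fid = acq$te_fid,
                 te_echo = acq$te_echo, tr = acq$ausfide_tr,
                 mask = array(TRUE, dim), noise_sd = 0),
            class = "ausfide_series")
}

test_that("rate decomposition is exact on pure exponentials", {
  ser <- pure_exp_series(25, 15)
  rates <- fit_decay_rates(ser)
  expect_equal(unique(round(rates$r2[rates$valid], 8)), 20)
  expect_equal(unique(round(rates$r2p[rates$valid], 8)), 5)
  expect_equal(unique(round(rates$r2star[rates$valid], 8)), 25)
  # R2* - R2 - R2' is zero by construction
  expect_true(all(abs(rates$r2star - rates$r2 - rates$r2p) < 1e-9,
                  na.rm = TRUE))
})

test_that("negative apparent R2' is clipped and flagged, bad voxels invalid", {
  ser <- pure_exp_series(15, 25)   # echo decays faster: R2' would be negative
  rates <- fit_decay_rates(ser)
  expect_true(all(rates$r2p[rates$valid] == 0))
  expect_true(all(rates$clipped[rates$valid]))
  ser$fid[1, 1, 1, ] <- 0
  rates2 <- fit_decay_rates(ser)
  expect_false(rates2$valid[1, 1, 1])
  expect_true(is.na(rates2$r2[1, 1, 1]))
})

test_that("R2' prior from the forward model lands within its bias budget", {
  ph <- tiny_phantom(yv = 0.6, dbv = 0.03, r2 = 20, r2p_nh = 1, db0 = 0)
  ser <- simulate_ausfide(ph, noise_sd = 0,
                          include_susceptibility_field = FALSE)
  rates <- fit_decay_rates(ser)
  truth <- 0.03 * delta_omega(0.44, 0.6) + 1
  est <- median(rates$r2p[ph$labels > 0], na.rm = TRUE)
  expect_lt(abs(est - truth) / truth, 0.10)
})

test_that("R2 is recovered within 2% at SNR 100 over hundreds of voxels", {
  ph <- tiny_phantom(dim = c(14, 14, 12), yv = 0.6, dbv = 0.03, r2 = 20,
                     r2p_nh = 1, db0 = 0)
  ser <- simulate_ausfide(ph, noise_sd = 1, seed = 21,
                          include_susceptibility_field = FALSE)
  rates <- fit_decay_rates(ser)
  tissue <- ph$labels > 0 & rates$valid
  expect_gt(sum(tissue), 500)
  err <- abs(rates$r2[tissue] - 20) / 20
  expect_lt(median(err), 0.02)
})

test_that("field mapping recovers offsets, including wrapped phase", {
  ph <- tiny_phantom(db0 = 0)
  ser0 <- simulate_ausfide(ph, noise_sd = 0,
                           include_susceptibility_field = FALSE)
  fm0 <- estimate_fieldmap(ser0)
  expect_true(all(abs(fm0$db0_ppm[ser0$mask]) < 1e-9))
  # 0.5 ppm at 3 T: absolute phase passes pi between echoes but the
  # per-spacing increment stays below pi, so unwrapping captures it
  ph$db0_ppm[] <- 0.5
  ser <- simulate_ausfide(ph, noise_sd = 0,
                          include_susceptibility_field = FALSE)
  rate <- physics_constants()$gamma * 3 * 0.5e-6
  expect_gt(rate * max(ser$te_fid), pi)          # wraps in absolute phase
  expect_lt(rate * 1.5e-3, pi)                   # within capture
  fm <- estimate_fieldmap(ser)
  expect_lt(max(abs(fm$db0_ppm[ser$mask] - 0.5)), 1e-9)
  expect_false(any(fm$aliased[ser$mask]))
})

test_that("dipole kernel and inversion satisfy the analytic limits", {
  d <- oxibold:::dipole_kernel(c(8, 8, 8))
  expect_equal(d[1, 1, 1], 0)            # k = 0 set to zero
  expect_equal(d[1, 1, 2], 1 / 3 - 1, tolerance = 1e-12)  # k along z
  expect_equal(d[2, 1, 1], 1 / 3, tolerance = 1e-12)      # kz = 0 plane
  zero <- invert_dipole(array(0, c(8, 8, 8)), reg = 1e-2)
  expect_true(all(zero$dchi_ppm == 0))
  expect_error(invert_dipole(array(0, c(8, 8, 8)), reg = 0), "reg")
})

test_that("dipole inversion round-trips a sphere and is linear", {
  n <- 32
  cx <- (1:n) - (n + 1) / 2
  X <- array(rep(cx, times = n * n), rep(n, 3))
  Y <- array(rep(rep(cx, each = n), times = n), rep(n, 3))
  Z <- array(rep(cx, each = n * n), rep(n, 3))
  D <- sqrt(X^2 + Y^2 + Z^2)
  chi <- array(0, rep(n, 3)); chi[D <= 6] <- 0.1
  fld <- dipole_field(chi)
  inv <- invert_dipole(fld, mask = array(TRUE, rep(n, 3)), reg = 1e-2,
                       detrend_order = 0)
  shell <- abs(D - 6) > 2
  rel_rmse <- sqrt(mean((inv$dchi_ppm - chi)[shell]^2)) / 0.1
  expect_lt(rel_rmse, 0.10)
  # linearity in the field
  inv2 <- invert_dipole(2 * fld, mask = array(TRUE, rep(n, 3)), reg = 1e-2,
                        detrend_order = 0)
  expect_equal(inv2$dchi_ppm, 2 * inv$dchi_ppm, tolerance = 1e-9)
})

test_that("CBVv quantification inverts the VS-VSL pair", {
  ph <- tiny_phantom(cbvv = 0.03, dbv = 0.03)
  pair <- simulate_vsvsl(ph, noise_sd = 0, m0b = 100)
  out <- quantify_cbvv(pair, m0b = 100)
  tissue <- ph$labels > 0
  expect_lt(max(abs(out$cbvv[tissue] - 0.03)), 1e-12)
  # worked inverse: difference 3.007 at the defaults is CBVv 0.03
  kappa <- exp(-1.14 / 1.65)
  expect_equal(3.006722 / (2 * kappa * 100), 0.03, tolerance = 1e-5)
  same <- quantify_cbvv(list(control = pair$control, tag = pair$control),
                        m0b = 100)
  expect_true(all(same$cbvv == 0))
  expect_error(quantify_cbvv(pair, m0b = 0), "positive")
})

test_that("CBF quantification matches the consensus formula and is linear", {
  acq <- acquisition_config()
  m0 <- array(100, c(4, 4, 4))
  dm <- array(1, c(4, 4, 4))   # dM/M0 = 0.01
  ser <- list(control = list(m0 + dm / 2), label = list(m0 - dm / 2), m0 = m0)
  out <- quantify_cbf(ser, acq = acq)
  expect_equal(out$cbf[1], 97.4209, tolerance = 1e-4)
  ser2 <- list(control = list(m0 + dm), label = list(m0 - dm), m0 = m0)
  expect_equal(quantify_cbf(ser2, acq = acq)$cbf, 2 * out$cbf,
               tolerance = 1e-9)
  ser0 <- list(control = list(m0), label = list(m0), m0 = m0)
  expect_true(all(quantify_cbf(ser0, acq = acq)$cbf == 0))
  m0bad <- m0; m0bad[1, 1, 1] <- 0
  outb <- quantify_cbf(list(control = list(m0 + dm), label = list(m0),
                            m0 = m0bad), acq = acq)
  expect_true(outb$invalid[1, 1, 1])
  expect_true(is.na(outb$cbf[1, 1, 1]))
})

test_that("prior-map errors grow monotonically with noise", {
  ph <- tiny_phantom(yv = 0.6, dbv = 0.03, r2 = 20, r2p_nh = 1, db0 = 0)
  tissue <- ph$labels > 0
  errs <- sapply(c(0, 1, 4), function(sd) {
    ser <- simulate_ausfide(ph, noise_sd = sd, seed = 33,
                            include_susceptibility_field = FALSE)
    rates <- fit_decay_rates(ser)
    median(abs(rates$r2[tissue] - 20), na.rm = TRUE)
  })
  expect_true(all(diff(errs) > 0))
})
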
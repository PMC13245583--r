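test_that("static dephasing function has the known limits and shape", {
  expect_identical(static_dephasing_fc(0), 0)
  # short-time quadratic regime: fc(x) ~ 0.3 x^2 within 5% for x <= 0.5
  xs <- c(0.1, 0.3, 0.5)
  fc <- static_dephasing_fc(xs)
  expect_true(all(abs(fc - 0.3 * xs^2) / fc < 0.05))
  # long-time unit slope: fc(20) - fc(19) ~ 1 within 5%
  d <- static_dephasing_fc(20) - static_dephasing_fc(19)
  expect_lt(abs(d - 1), 0.05)
  # monotone nondecreasing over a dense grid
  grid <- static_dephasing_fc(seq(0, 30, length.out = 100), "spline")
  expect_true(all(diff(grid) >= -1e-12))
  # interpolation table agrees with adaptive quadrature
  probe <- c(0.07, 0.9, 3.3, 17.2, 45)
  expect_lt(max(abs(static_dephasing_fc(probe, "spline") -
                      static_dephasing_fc(probe))), 1e-5)
  expect_error(static_dephasing_fc(-1), "nonnegative")
})

test_that("characteristic frequency matches its closed form", {
  expect_identical(delta_omega(0.44, 1), 0)
  # worked value at 3 T defaults
  expect_equal(delta_omega(0.44, 0.60), 159.7464, tolerance = 1e-6)
  # proportional to (1 - yv)
  expect_equal(delta_omega(0.3, 0.2), 2 * delta_omega(0.3, 0.6))
  expect_error(delta_omega(1.5, 0.5), "\\[0, 1\\]")
})

test_that("qBOLD signal reduces to mono-exponentials without deoxyhemoglobin", {
  st <- voxel_state(dbv = 0, r2p_nh = 0, r2 = 20)
  acq <- acquisition_config()
  te <- seq(0.003, 0.025, by = 0.002)
  f <- Mod(qbold_signal(st, acq, "fid", te))
  e <- Mod(qbold_signal(st, acq, "echo", te))
  expect_equal(f, st$a_fid * exp(-20 * te), tolerance = 1e-12)
  expect_equal(log_slope(f, te), -20, tolerance = 1e-9)
  expect_equal(log_slope(e, te), -20, tolerance = 1e-9)
  # te -> 0 recovers the FID amplitude exactly
  expect_equal(Mod(qbold_signal(st, acq, "fid", 0)), st$a_fid)
})

test_that("effective decay rates are R2 +/- R2' in the linear regime", {
  # truth R2' = dbv*domega + r2p_nh = 0.03 * 159.75 + 1 = 5.79
  st <- voxel_state(yv = 0.6, dbv = 0.03, r2 = 20, r2p_nh = 1, hct = 0.44)
  acq <- acquisition_config()
  r2p <- 0.03 * delta_omega(0.44, 0.6) + 1
  te_fid <- seq(0.015, 0.025, by = 0.001)  # delta-omega * te >= 2.4
  sf <- log_slope(Mod(qbold_signal(st, acq, "fid", te_fid)), te_fid)
  expect_lt(abs(sf - (-(20 + r2p))) / (20 + r2p), 0.03)
  # ECHO linear regime is where TR - te is large, i.e. early echoes
  te_echo <- seq(0.0022, 0.009, by = 0.001)
  se <- log_slope(Mod(qbold_signal(st, acq, "echo", te_echo)), te_echo)
  expect_lt(abs(se - (-(20 - r2p))) / (20 - r2p), 0.03)
  expect_error(qbold_signal(st, acq, "echo", acq$ausfide_tr), "repetition")
})

test_that("susceptibility model combines the four pools correctly", {
  cst <- physics_constants()
  st0 <- voxel_state(cbva = 0, cbvv = 0, chi_nb = 0.05)
  expect_equal(susceptibility_model(st0), 0.05)
  # term-by-term hand evaluation
  st <- voxel_state(yv = 0.6, cbvv = 0.03, cbva = 0.01, hct = 0.44,
                    chi_nb = 0)
  art <- -0.03 + 0.44 * 0.27 * (1 - 0.98)
  ven <- -0.03 + 0.44 * 0.27 * (1 - 0.60)
  expect_equal(susceptibility_model(st), 0.01 * art + 0.03 * ven,
               tolerance = 1e-12)
  # venous pool at arterial saturation with matched tissue susceptibility
  st2 <- voxel_state(yv = 0.98, chi_nb = -0.03, cbvv = 0.03, cbva = 0.01)
  expect_equal(susceptibility_model(st2),
               -0.03 + (0.01 + 0.03) * 0.44 * 0.27 * 0.02, tolerance = 1e-12)
  st_bad <- voxel_state()
  st_bad$cbva <- 0.9; st_bad$cbvv <- 0.2
  expect_error(susceptibility_model(st_bad), "sum")
})

test_that("R2' decomposition is heme plus non-heme", {
  expect_equal(r2prime_model(voxel_state(dbv = 0, r2p_nh = 0)), 0)
  st <- voxel_state(yv = 0.6, dbv = 0.03, r2p_nh = 1.5, hct = 0.44)
  expect_equal(r2prime_model(st), 0.03 * delta_omega(0.44, 0.6) + 1.5,
               tolerance = 1e-12)
  # monotone decreasing in yv at fixed dbv
  vals <- sapply(c(0.5, 0.6, 0.7, 0.8), function(yv)
    r2prime_model(voxel_state(yv = yv, dbv = 0.03, r2p_nh = 1)))
  expect_true(all(diff(vals) < 0))
})

test_that("Fick's principle has the right units and linearity", {
  expect_identical(fick_cmro2(50, 0.44, 0), 0)
  expect_equal(fick_cmro2(50, 0.44, 0.35), 150.3918, tolerance = 1e-4)
  # unit constant: CBF 1, Hct 1, OEF 1 gives C_rbc * SaO2 exactly
  expect_equal(fick_cmro2(1, 1, 1), 19.5314, tolerance = 1e-10)
  expect_equal(fick_cmro2(100, 0.44, 0.35), 2 * fick_cmro2(50, 0.44, 0.35))
  expect_error(fick_cmro2(-1, 0.4, 0.3), ">= 0")
})

test_that("OEF-Yv conversion round-trips and clips", {
  expect_equal(as.numeric(oef_from_yv(0.98)), 0)
  expect_equal(as.numeric(oef_from_yv(0.588)), 0.40, tolerance = 1e-12)
  oef <- c(0.2, 0.35, 0.6)
  expect_equal(as.numeric(oef_from_yv(yv_from_oef(oef))), oef,
               tolerance = 1e-12)
  expect_warning(out <- oef_from_yv(0.99), "clipped")
  expect_equal(as.numeric(out), 0)
  expect_identical(attr(out, "clipped"), 1L)
})
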
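test_that("without reversible dephasing the FID is a pure exponential", {
  ph <- tiny_phantom(dbv = 0, r2p_nh = 0, r2 = 20, db0 = 0)
  ser <- simulate_ausfide(ph, noise_sd = 0, a_fid = 100,
                          include_susceptibility_field = FALSE)
  idx <- which(ph$labels > 0)[1]
  nv <- prod(ph$dim)
  mag <- sapply(seq_along(ser$te_fid), function(k) abs(ser$fid[idx + (k - 1) * nv]))
  expect_equal(mag, 100 * exp(-20 * ser$te_fid), tolerance = 1e-12)
})

test_that("simulated decays carry R2 + R2' (FID) and R2 - R2' (ECHO)", {
  ph <- tiny_phantom(yv = 0.6, dbv = 0.03, r2 = 20, r2p_nh = 1, db0 = 0)
  ser <- simulate_ausfide(ph, noise_sd = 0,
                          include_susceptibility_field = FALSE)
  idx <- which(ph$labels > 0)[1]
  nv <- prod(ph$dim)
  mf <- sapply(1:17, function(k) abs(ser$fid[idx + (k - 1) * nv]))
  me <- sapply(1:17, function(k) abs(ser$echo[idx + (k - 1) * nv]))
  r2p <- 0.03 * delta_omega(0.44, 0.6) + 1
  late <- ser$te_fid >= 0.015              # linear regime of the FID
  sf <- log_slope(mf[late], ser$te_fid[late])
  expect_lt(abs(sf + 20 + r2p) / (20 + r2p), 0.03)
  early <- ser$te_echo <= 0.009            # linear regime of the ECHO
  se <- log_slope(me[early], ser$te_echo[early])
  expect_lt(abs(se + 20 - r2p) / (20 - r2p), 0.03)
})

test_that("noise is seeded, scaled, and isolated from the signal", {
  ph <- tiny_phantom()
  expect_error(simulate_ausfide(ph, noise_sd = -1), "nonnegative")
  s1 <- simulate_ausfide(ph, noise_sd = 2, seed = 10)
  s2 <- simulate_ausfide(ph, noise_sd = 2, seed = 10)
  expect_identical(s1$fid, s2$fid)
  # per-channel noise SD recovered from >= 1000 residual samples
  s0 <- simulate_ausfide(ph, noise_sd = 0)
  resid <- Re(s1$fid - s0$fid)
  expect_gt(length(resid), 1000)
  expect_lt(abs(sd(resid) - 2) / 2, 0.05)
})

test_that("VS-VSL difference isolates the venous signal", {
  ph0 <- tiny_phantom(cbvv = 0, dbv = 0)
  pair0 <- simulate_vsvsl(ph0, noise_sd = 0)
  expect_true(all(pair0$control - pair0$tag == 0))
  # worked value: 2 * exp(-1.14/1.65) * 100 * 0.03
  ph <- tiny_phantom(cbvv = 0.03, dbv = 0.03)
  pair <- simulate_vsvsl(ph, noise_sd = 0, m0b = 100)
  d <- (pair$control - pair$tag)[ph$labels > 0]
  expect_equal(unique(round(d, 9)), round(2 * exp(-1.14 / 1.65) * 100 * 0.03, 9))
  expect_equal(d[1], 3.006722, tolerance = 1e-5)
  # determinism under noise
  pa <- simulate_vsvsl(ph, noise_sd = 1, seed = 4)
  pb <- simulate_vsvsl(ph, noise_sd = 1, seed = 4)
  expect_identical(pa$control, pb$control)
})

test_that("pCASL simulation inverts the consensus quantification exactly", {
  ph0 <- tiny_phantom()
  ph0$maps$cbf[!is.na(ph0$maps$cbf)] <- 0
  ser0 <- simulate_pcasl(ph0, noise_sd = 0)
  expect_true(all(mapply(function(c, l) all(c - l == 0),
                         ser0$control, ser0$label)))
  ph <- tiny_phantom()
  ser <- simulate_pcasl(ph, noise_sd = 0)
  # all noiseless pairs identical
  expect_length(ser$control, 6L)
  expect_identical(ser$control[[1]], ser$control[[6]])
  cbf <- quantify_cbf(ser)
  tissue <- ph$labels > 0
  expect_lt(max(abs(cbf$cbf[tissue] - ph$maps$cbf[tissue])), 1e-9)
  # the worked ratio: CBF 97.42 at the defaults corresponds to dM/M0 = 0.01
  ph2 <- tiny_phantom()
  ph2$maps$cbf[!is.na(ph2$maps$cbf)] <- 97.4209
  ser2 <- simulate_pcasl(ph2, noise_sd = 0, m0 = 100)
  dm <- (ser2$control[[1]] - ser2$label[[1]])[ph2$labels > 0][1]
  expect_equal(dm / 100, 0.01, tolerance = 1e-5)
})

test_that("phase processing sees the configured field offset", {
  ph <- tiny_phantom(db0 = 0)
  ph$db0_ppm[] <- 0.1
  ser <- simulate_ausfide(ph, noise_sd = 0,
                          include_susceptibility_field = FALSE)
  fm <- estimate_fieldmap(ser)
  expect_lt(max(abs(fm$db0_ppm[ser$mask] - 0.1)), 1e-9)
})
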
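test_that("noiseless voxel with exact priors is recovered near-exactly", {
  truth <- c(yv = 0.60, dbv = 0.03, r2p_nh = 1.0, chi_nb = 0.02)
  mags <- voxel_magnitudes(0.60, 0.03, 20, 1.0)
  pr <- voxel_priors(0.60, 0.03, 20, 1.0, chi_nb = 0.02)
  fit <- fit_qbold_voxel(mags$fid, mags$echo, pr, hct = 0.44)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$theta[names(truth)] - truth)), 1e-4)
  expect_lt(abs(fit$r2 - 20), 1e-3)
  # multistart agrees (local convexity near the truth)
  fit5 <- fit_qbold_voxel(mags$fid, mags$echo, pr, hct = 0.44,
                          weights = fit_weights(multistart = 5))
  expect_lt(max(abs(fit5$theta[names(truth)] - truth)), 1e-4)
})

test_that("zero-extraction voxel yields near-zero OEF", {
  mags <- voxel_magnitudes(0.98, 0.03, 20, 1.0)
  pr <- voxel_priors(0.98, 0.03, 20, 1.0)
  fit <- fit_qbold_voxel(mags$fid, mags$echo, pr, hct = 0.44)
  expect_lt(fit$oef, 0.005)
})

test_that("penalty-free noiseless fit matches the penalised one", {
  mags <- voxel_magnitudes(0.62, 0.025, 16, 1.2)
  pr <- voxel_priors(0.62, 0.025, 16, 1.2)
  f0 <- fit_qbold_voxel(mags$fid, mags$echo, pr, hct = 0.44,
                        weights = fit_weights(w = 0, p = 0, w_dbv = 0,
                                              p_r2 = 0))
  f1 <- fit_qbold_voxel(mags$fid, mags$echo, pr, hct = 0.44)
  expect_lt(abs(f0$theta[["yv"]] - 0.62), 1e-4)
  expect_lt(abs(f0$theta[["yv"]] - f1$theta[["yv"]]), 2e-4)
  # penalty consistency at the solution with consistent data
  st <- voxel_state(yv = f1$theta[["yv"]], dbv = f1$theta[["dbv"]],
                    r2 = f1$r2, r2p_nh = f1$theta[["r2p_nh"]],
                    chi_nb = f1$theta[["chi_nb"]], cbvv = 0.025)
  expect_lt(abs(pr$dchi - susceptibility_model(st)), 1e-6)
  expect_lt(abs(pr$r2p - r2prime_model(st)), 1e-6)
})

test_that("a corrupted susceptibility prior pulls the objective minimum monotonically", {
  mags <- voxel_magnitudes(0.60, 0.03, 20, 1.0)
  pr <- voxel_priors(0.60, 0.03, 20, 1.0, chi_nb = 0.01)
  pr_bad <- pr
  pr_bad$dchi <- pr$dchi + 0.5        # far beyond what chi_nb bounds absorb
  # 1-D scan of the objective in yv with the other parameters held at truth
  yv_grid <- seq(0.40, 0.95, by = 0.0025)
  argmin_yv <- sapply(c(0, 1e4, 1e6, 1e8), function(w) {
    obj <- sapply(yv_grid, function(yv)
      qbold_objective(c(yv, 0.03, 1.0, 0.2), mags$fid, mags$echo, pr_bad,
                      hct = 0.44, w = w, p = 0))
    yv_grid[which.min(obj)]
  })
  # with chi_nb saturated at its bound, larger w drags yv toward the value
  # that makes Psi match the (corrupted, higher) susceptibility prior:
  # higher dchi needs more deoxyhemoglobin, i.e. lower yv
  expect_equal(argmin_yv[1], 0.60, tolerance = 0.005)
  expect_true(all(diff(argmin_yv) <= 1e-12))
  expect_lt(argmin_yv[4], argmin_yv[1])
})

test_that("parameter sweep is recovered within 1% on noiseless voxels", {
  set.seed(19)
  n <- 200
  yv <- runif(n, 0.5, 0.8)
  dbv <- runif(n, 0.01, 0.06)
  worst <- 0
  for (i in seq_len(n)) {
    mags <- voxel_magnitudes(yv[i], dbv[i], 18, 1.0)
    pr <- voxel_priors(yv[i], dbv[i], 18, 1.0)
    fit <- fit_qbold_voxel(mags$fid, mags$echo, pr, hct = 0.44)
    worst <- max(worst,
                 abs(fit$theta[["yv"]] - yv[i]) / yv[i],
                 abs(fit$theta[["dbv"]] - dbv[i]) / dbv[i])
  }
  expect_lt(worst, 0.01)
})

test_that("the optimizer objective never increases along its trace", {
  set.seed(5)
  for (i in 1:20) {
    yv <- runif(1, 0.5, 0.8)
    mags <- voxel_magnitudes(yv, 0.03, 18, 1.0)
    pr <- voxel_priors(yv, 0.03, 18, 1.0)
    yf <- abs(mags$fid + rnorm(17))
    ye <- abs(mags$echo + rnorm(17))
    fit <- suppressWarnings(fit_qbold_voxel(yf, ye, pr, hct = 0.44))
    expect_true(all(diff(fit$rsstrace) <= 1e-10))
  }
})

test_that("penalties trade variance for bias monotonically", {
  mags <- voxel_magnitudes(0.638, 0.03, 14, 0.8)
  pr <- voxel_priors(0.638, 0.03, 14, 0.8)
  sds <- sapply(list(c(0, 0), c(1e3, 1), c(1e5, 100)), function(lev) {
    set.seed(7)
    oefs <- replicate(30, {
      yf <- abs(mags$fid + rnorm(17))
      ye <- abs(mags$echo + rnorm(17))
      wts <- fit_weights(w = lev[1], p = lev[2], p_r2 = lev[2],
                         w_dbv = lev[1] * 40)
      suppressWarnings(fit_qbold_voxel(yf, ye, pr, 0.44,
                                       weights = wts)$oef)
    })
    sd(oefs)
  })
  expect_true(all(diff(sds) < 0))
})

test_that("volume fitting handles masks, grids, and CMRO2 composition", {
  ph <- tiny_phantom(dim = c(8, 8, 8))
  ser <- simulate_ausfide(ph, noise_sd = 0)
  pr <- fit_prior_maps(ser, simulate_vsvsl(ph), simulate_pcasl(ph))
  # empty mask: empty result, no error
  res0 <- fit_qbold(ser, pr, hct = 0.44,
                    mask = array(FALSE, dim(ph$labels)))
  expect_equal(res0$summary$n_voxels, 0)
  # grid mismatch fails before fitting
  pr_bad <- pr
  pr_bad$r2 <- array(20, c(4, 4, 4))
  expect_error(fit_qbold(ser, pr_bad, hct = 0.44), "mismatch")
  # CMRO2 map identity: CMRO2 / (CBF * OEF) = Hct * C_rbc * SaO2
  res <- fit_qbold(ser, pr, hct = 0.44)
  ok <- is.finite(res$cmro2) & res$cmro2 > 0
  ratio <- res$cmro2[ok] / (pr$cbf[ok] * res$oef[ok])
  expect_equal(unique(round(ratio, 6)), round(0.44 * 19.93 * 0.98, 6))
  # OEF identity holds voxelwise
  expect_equal(res$oef[ok], (0.98 - res$yv[ok]) / 0.98, tolerance = 1e-12)
})

test_that("uniform inputs give the worked CMRO2 value", {
  oef <- array(0.35, c(4, 4, 4))
  cbf <- array(50, c(4, 4, 4))
  out <- cmro2_map(list(oef = oef), cbf, hct = 0.44)
  expect_equal(unique(round(as.numeric(out), 4)), 150.3918)
  out0 <- cmro2_map(list(oef = array(0, c(2, 2, 2))), array(50, c(2, 2, 2)),
                    hct = 0.44)
  expect_true(all(out0 == 0))
  expect_error(cmro2_map(list(oef = oef), cbf, hct = 1.5), "scalar in")
})
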
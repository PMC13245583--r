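test_that("mask preparation resamples, erodes, and respects hierarchy", {
  ph <- make_digital_phantom(dim = c(20, 20, 16))
  masks <- prepare_masks(ph$labels, erode_wm = FALSE)
  # identity resampling
  expect_equal(dim(masks$wb), dim(ph$labels))
  expect_true(all(masks$hc & masks$mtl | !masks$hc))   # hc inside mtl
  expect_true(all(masks$fl & masks$gm | !masks$fl))    # lobes inside gm
  expect_false(any(masks$gm & masks$wm))
  # 3x3x3 solid cube erodes to its center voxel
  cube <- array(0L, c(5, 5, 5))
  cube[2:4, 2:4, 2:4] <- 2L   # wm code
  m <- prepare_masks(cube, erode_wm = TRUE, rois = "wm")
  expect_equal(sum(m$wm), 1L)
  expect_true(m$wm[3, 3, 3])
  # 2x downsampling of a uniform block keeps its label
  blk <- array(1L, c(8, 8, 8))
  m2 <- prepare_masks(blk, target_dim = c(4, 4, 4), rois = "gm")
  expect_true(all(m2$gm))
  expect_error(prepare_masks(array(0.5, c(8, 8, 8))), "integer")
})

test_that("ROI summary trims by within-ROI percentiles", {
  m <- array(as.numeric(1:100), c(10, 10, 1))
  s <- roi_summary(m, array(TRUE, dim(m)))
  expect_equal(s$n_kept, 90L)
  expect_equal(s$mean, 50.5)
  # implausible values are filtered before trimming
  m2 <- array(c(-1, 0, Inf, 5), c(4, 1, 1))
  s2 <- roi_summary(m2, array(TRUE, dim(m2)))
  expect_equal(s2$n_plausible, 1L)
  expect_equal(s2$mean, 5)
  expect_true(s2$low_confidence)
  # constant maps are fully retained
  m3 <- array(7, c(5, 5, 1))
  s3 <- roi_summary(m3, array(TRUE, dim(m3)))
  expect_equal(s3$n_kept, 25L)
  expect_equal(s3$mean, 7)
  expect_error(roi_summary(m3, array(FALSE, dim(m3))), "empty")
})

test_that("percentile trimming retains 89-91% of distinct values", {
  set.seed(31)
  for (n in c(100, 250, 1000)) {
    v <- array(sort(runif(n, 1, 100)), c(n, 1, 1))
    s <- roi_summary(v, array(TRUE, dim(v)))
    expect_gte(s$n_kept / n, 0.89)
    expect_lte(s$n_kept / n, 0.91)
  }
})

test_that("group comparison gates on normality", {
  r0 <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$test, "t")
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  set.seed(3)
  a <- rnorm(15); b <- rnorm(19, mean = 1)
  r1 <- compare_groups(a, b)
  expect_equal(r1$test, "t")
  expect_lt(r1$p, 0.05)
  set.seed(17)
  bexp <- rexp(19, rate = 0.2)
  expect_lt(shapiro.test(bexp)$p.value, 0.05)  # the gate must reject
  r2 <- compare_groups(rnorm(15, 5), bexp)
  expect_equal(r2$test, "mann_whitney_u")
  expect_error(compare_groups(1:2, 1:5), ">= 3")
})

test_that("group-comparison type-I error is near nominal under the null", {
  set.seed(101)
  p <- replicate(2000, compare_groups(rnorm(15), rnorm(19))$p)
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
})

test_that("paired region-vs-global comparison behaves symmetrically", {
  x <- rnorm(12, 40, 3)
  r0 <- compare_region_to_global(x, x)
  expect_equal(r0$p, 1)
  expect_equal(r0$estimate, 0)
  set.seed(9)
  g <- rnorm(15, 40, 3)
  d <- 2 + rnorm(15, 0, 0.05)
  r1 <- compare_region_to_global(g + d, g)
  expect_equal(r1$estimate, 2, tolerance = 0.05)
  expect_lt(r1$p, 0.001)
  expect_gt(abs(r1$effect_size), 5)
  r2 <- compare_region_to_global(g - d, g)
  expect_equal(r2$estimate, -r1$estimate)
  expect_equal(r2$effect_size, -r1$effect_size)
  expect_equal(r2$p, r1$p)
})

test_that("BH adjustment matches a brute-force oracle and p.adjust", {
  expect_equal(bh_adjust(0.037), 0.037)
  # brute force: q(i) = min over j with p(j) >= p(i) of p(j) * m / rank(j)
  brute <- function(p) {
    m <- length(p)
    o <- order(p)
    r <- numeric(m)
    sorted <- p[o]
    for (i in seq_len(m)) {
      r[o[i]] <- min(pmin(sorted[i:m] * m / (i:m), 1))
    }
    r
  }
  set.seed(77)
  for (rep in 1:1000) {
    p <- runif(sample(1:20, 1))
    q <- bh_adjust(p)
    expect_equal(q, brute(p), tolerance = 1e-12)
  }
  # independent implementation cross-check and elementwise properties
  set.seed(78)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
  expect_true(all(q >= p))
  expect_equal(order(q[order(p)]), seq_along(p))  # order preserved
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("published q-values are reproduced from the stored p-value table", {
  tab <- reference_group_pvalues()
  expect_equal(nrow(tab), 33L)
  cm <- tab[tab$family == "cmro2", ]
  q_cm <- bh_adjust(cm$p)
  expect_equal(round(q_cm[cm$region == "ag"], 3), 0.121)
  cb <- tab[tab$family == "cbf", ]
  q_cb <- bh_adjust(cb$p)
  expect_equal(round(q_cb[cb$region == "wm"], 3), 0.425)
  expect_equal(round(q_cb[cb$region == "ag"], 3), 0.222)
})

test_that("Pearson correlation matches the t transform and a permutation null", {
  r1 <- pearson_age_corr(1:10, 2 * (1:10) + 1)
  expect_equal(r1$r, 1)
  r2 <- pearson_age_corr(1:10, -(1:10))
  expect_equal(r2$r, -1)
  set.seed(12)
  n <- 20
  x <- rnorm(n); y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(n)
  res <- pearson_age_corr(x, y)
  expect_gt(res$r, 0.2); expect_lt(res$r, 0.9)
  # permutation oracle for the p-value
  obs <- abs(cor(x, y))
  perm <- replicate(1e4, abs(cor(x, sample(y))))
  p_perm <- mean(perm >= obs)
  expect_lt(abs(res$p - p_perm), max(0.01, 3 * sqrt(p_perm * (1 - p_perm) / 1e4)))
  expect_true(is.na(pearson_age_corr(rep(1, 5), rnorm(5))$r))
})

test_that("laterality indices behave antisymmetrically", {
  r0 <- laterality(rep(10, 8), rep(10, 8))
  expect_equal(r0$mean_li, 0)
  expect_equal(r0$p, 1)
  expect_equal((11 - 9) / (11 + 9), 0.1)
  set.seed(6)
  right <- rnorm(15, 11, 0.3); left <- rnorm(15, 9, 0.3)
  r1 <- laterality(right, left)
  expect_lt(abs(r1$mean_li - 0.1), 0.02)
  r2 <- laterality(left, right)
  expect_equal(r2$mean_li, -r1$mean_li)
  expect_equal(r2$p, r1$p)
})

test_that("volumetric normalisation matches hand arithmetic", {
  v <- volumetrics(685.2, 493.9, 300.0)
  expect_equal(v$icv, 1479.1)
  expect_equal(v$gm_picv, 100 * 685.2 / 1479.1, tolerance = 1e-9)
  expect_equal(round(v$gm_picv, 2), 46.33)
  v0 <- volumetrics(600, 400, 0)
  expect_equal(v0$wb_picv, 100)
  # scale invariance
  v2 <- volumetrics(2 * 685.2, 2 * 493.9, 2 * 300.0)
  expect_equal(v2$gm_picv, v$gm_picv)
  expect_equal(v2$gm_wb, v$gm_wb)
  expect_error(volumetrics(0, 0, 0), "ICV")
})

test_that("2x2 chi-square reproduces printed and analytic values", {
  r0 <- chi_square_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  # published sex-balance table
  r1 <- chi_square_2x2(reference_sex_counts())
  expect_equal(round(r1$p, 3), 0.982)
  # n(ad - bc)^2 / (margin product) for a perfectly separated table
  r2 <- chi_square_2x2(matrix(c(20, 0, 0, 20), 2))
  expect_equal(r2$statistic, 40)
  expect_error(chi_square_2x2(matrix(c(1, 0, 2, 0), 2)), "margin")
})

test_that("age regression recovers exact linear structure", {
  set.seed(4)
  n <- 40
  coh <- tibble::tibble(
    subject_id = as.character(1:n),
    group = rep(c("young", "old"), each = n / 2),
    age_years = seq(20, 80, length.out = n),
    sex = rep(c("M", "F"), n / 2),
    gm_vol = rnorm(n, 650, 40), wm_vol = rnorm(n, 480, 30),
    csf_vol = rnorm(n, 300, 25)
  )
  coh$wb_oef <- 30 + 0.15 * coh$age_years
  m <- suppressWarnings(fit_age_model(coh, "oef", "wb"))
  co <- generics::tidy(m)
  expect_equal(co$estimate[co$term == "age"], 0.150, tolerance = 1e-10)
  expect_lt(co$std_error[co$term == "age"], 1e-8)
  expect_equal(co$estimate[co$term == "sex"], 0, tolerance = 1e-8)
  expect_equal(glance(m)$r_squared, 1, tolerance = 1e-9)
  # univariate standardized slope equals the Pearson correlation
  coh$wb_oef <- coh$wb_oef + rnorm(n, 0, 2)
  m1 <- fit_age_model(coh, "oef", "wb", covariates = "age")
  r <- cor(coh$age_years, coh$wb_oef)
  expect_equal(generics::tidy(m1)$std_beta[2], r, tolerance = 1e-12)
})

test_that("collinear covariates raise a named error", {
  coh <- simulate_cohort(cohort_config(seed = 2))
  coh$sex <- "M"   # degenerate: no variance in the sex covariate
  expect_error(fit_age_model(coh, "oef", "wb"), "[Cc]ollinear.*sex")
})

test_that("generative slope is recovered inside its own confidence interval", {
  rp <- default_cohort_params()
  rp$oef_old <- rp$oef_young + rp$oef_slope * 39.5   # colinear anchors
  rp[grepl("oef_sd", names(rp))] <- 3
  cfg <- cohort_config(n_young = 100, n_old = 100, region_params = rp,
                       seed = 5)
  coh <- simulate_cohort(cfg)
  m <- fit_age_model(coh, "oef", "wb")
  co <- generics::tidy(m)
  age <- co[co$term == "age", ]
  expect_gt(0.150, age$ci_low)
  expect_lt(0.150, age$ci_high)
})
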
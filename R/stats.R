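#' Resample a label volume and build per-region masks
#'
#' Nearest-neighbour resampling of an integer label volume to a target grid,
#' followed by construction of boolean ROI masks. ROIs follow the designed
#' hierarchy (gray matter includes the cortical lobes; the medial temporal
#' lobe includes hippocampus and amygdala); all other region masks are
#' mutually disjoint. The white matter mask can be eroded with a 3x3x3
#' structuring element to strip boundary voxels.
#'
#' @param labels Integer 3-D label array ([phantom_labels()] codes).
#' @param target_dim Target grid dimensions (default: unchanged).
#' @param erode_wm Erode the white matter mask by one voxel.
#' @param rois Character vector of ROI names to build.
#' @return Named list of logical arrays, one per ROI, with attribute
#'   `unknown_labels` listing any codes present in `labels` that no ROI
#'   claims.
#' @export
prepare_masks <- function(labels, target_dim = dim(labels),
                          erode_wm = TRUE, rois = cohort_regions()) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    abort("`labels` must be a 3-D array.")
  }
  if (any(labels != round(labels), na.rm = TRUE)) {
    abort("`labels` must be integer-valued.")
  }
  lab <- resample_nn(labels, target_dim)
  known <- unlist(lapply(rois, region_members))
  unknown <- setdiff(unique(as.integer(lab)), c(0L, known, phantom_labels()))
  if (length(unknown)) {
    warn(sprintf("Label codes with no ROI assignment: %s",
                 paste(unknown, collapse = ", ")))
  }
  masks <- lapply(rois, function(r) array(lab %in% region_members(r), dim(lab)))
  names(masks) <- rois
  if (erode_wm && "wm" %in% rois) masks$wm <- erode3(masks$wm)
  attr(masks, "unknown_labels") <- unknown
  masks
}

resample_nn <- function(vol, target_dim) {
  src <- dim(vol)
  target_dim <- as.integer(target_dim)
  if (all(src == target_dim)) return(vol)
  idx <- lapply(1:3, function(a) {
    i <- pmin(pmax(floor((seq_len(target_dim[a]) - 0.5) * src[a] /
                           target_dim[a]) + 1L, 1L), src[a])
    i
  })
  vol[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# binary erosion with a full 3x3x3 box; outside the volume counts as FALSE
erode3 <- function(mask) {
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  out <- array(TRUE, d)
  for (dx in 0:2) for (dy in 0:2) for (dz in 0:2) {
    out <- out & pad[(1 + dx):(d[1] + dx),
                     (1 + dy):(d[2] + dy),
                     (1 + dz):(d[3] + dz)]
  }
  out
}

#' ROI summary with plausibility filtering and percentile trimming
#'
#' Restricts a parametric map to an ROI mask, keeps physiologically
#' plausible values (finite and strictly positive), trims values below the
#' 5th or above the 95th percentile of the plausible set (percentiles by the
#' linear-interpolation convention, computed within the ROI), and summarises
#' the retained voxels.
#'
#' @param map Numeric array.
#' @param mask Logical array (nonempty).
#' @param probs Lower/upper trimming percentiles (default `c(0.05, 0.95)`).
#' @return One-row tibble: `n_total`, `n_plausible`, `n_kept`, `mean`, `sd`,
#'   `low_confidence`.
#' @examples
#' m <- array(c(1:100), c(10, 10, 1))
#' roi_summary(m, array(TRUE, dim(m)))
#' @export
roi_summary <- function(map, mask, probs = c(0.05, 0.95)) {
  if (!any(mask)) abort("ROI mask is empty.")
  v <- map[mask]
  plausible <- v[is.finite(v) & v > 0]
  if (length(plausible) < 2L) {
    return(tibble::tibble(
      n_total = sum(mask), n_plausible = length(plausible),
      n_kept = length(plausible),
      mean = if (length(plausible)) mean(plausible) else NA_real_,
      sd = NA_real_, low_confidence = TRUE))
  }
  q <- quantile(plausible, probs, type = 7, names = FALSE)
  kept <- plausible[plausible >= q[1] & plausible <= q[2]]
  tibble::tibble(n_total = sum(mask), n_plausible = length(plausible),
                 n_kept = length(kept), mean = mean(kept), sd = sd(kept),
                 low_confidence = FALSE)
}

# Shapiro-Wilk normality gate; constant samples are treated as non-normal
# (the downstream tests handle them explicitly)
is_normal <- function(x, alpha = 0.05) {
  if (length(x) < 3L || length(unique(x)) == 1L) return(FALSE)
  p <- tryCatch(shapiro.test(x)$p.value, error = function(e) NA_real_)
  !is.na(p) && p > alpha
}

test_result <- function(test, statistic, p, ci = c(NA_real_, NA_real_),
                        effect = NA_real_, normal = NA, flag = NA_character_,
                        estimate = NA_real_) {
  tibble::tibble(test = test, statistic = statistic, estimate = estimate,
                 p = p, ci_low = ci[1], ci_high = ci[2],
                 effect_size = effect, normal_gate = normal, flag = flag)
}

#' Two-group comparison with a normality gate
#'
#' Shapiro-Wilk normality is assessed per group at alpha = 0.05; when both
#' groups pass, a two-sided equal-variance (Student) independent-samples
#' t-test is used, otherwise a two-sided Mann-Whitney U test with normal
#' approximation and tie correction (no continuity correction).
#'
#' @param a,b Numeric vectors (each length >= 3).
#' @param welch Use Welch's t-test instead of Student's when gated parametric.
#' @return One-row tibble (`test`, `statistic`, `estimate` = mean difference
#'   a - b, `p`, CI of the mean difference where defined, `normal_gate`,
#'   `flag`).
#' @export
compare_groups <- function(a, b, welch = FALSE) {
  if (length(a) < 3L || length(b) < 3L) abort("Need >= 3 values per group.")
  if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) {
    return(test_result("t", 0, 1, normal = NA, flag = "degenerate",
                       estimate = 0))
  }
  norm <- is_normal(a) && is_normal(b)
  if (norm) {
    tt <- t.test(a, b, var.equal = !welch)
    test_result(if (welch) "welch_t" else "t", unname(tt$statistic),
                tt$p.value, ci = unname(tt$conf.int),
                normal = TRUE, estimate = mean(a) - mean(b))
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = FALSE))
    test_result("mann_whitney_u", unname(wt$statistic), wt$p.value,
                normal = FALSE, estimate = mean(a) - mean(b))
  }
}

#' Paired region-versus-global comparison
#'
#' Differences `d = region - global` per subject; Shapiro-Wilk on `d` gates
#' a paired t-test versus a Wilcoxon signed-rank test (zeros dropped, normal
#' approximation). Reports the mean difference, its 95% CI, and Cohen's
#' dz = mean(d) / sd(d).
#'
#' @param region_vals,global_vals Numeric vectors, paired by subject.
#' @return One-row tibble.
#' @export
compare_region_to_global <- function(region_vals, global_vals) {
  if (length(region_vals) != length(global_vals)) {
    abort("Paired vectors must have equal length.")
  }
  d <- region_vals - global_vals
  if (all(d == 0)) {
    return(test_result("paired_t", 0, 1, ci = c(0, 0), effect = 0,
                       normal = NA, flag = "all_zero", estimate = 0))
  }
  dz <- if (sd(d) > 0) mean(d) / sd(d) else NA_real_
  if (is_normal(d)) {
    tt <- t.test(d, mu = 0)
    test_result("paired_t", unname(tt$statistic), tt$p.value,
                ci = unname(tt$conf.int), effect = dz, normal = TRUE,
                estimate = mean(d))
  } else {
    wt <- suppressWarnings(wilcox.test(d[d != 0], mu = 0, exact = FALSE))
    se <- sd(d) / sqrt(length(d))
    ci <- mean(d) + qt(c(0.025, 0.975), length(d) - 1) * se
    test_result("wilcoxon_signed_rank", unname(wt$statistic), wt$p.value,
                ci = ci, effect = dz, normal = FALSE, estimate = mean(d))
  }
}

#' Benjamini-Hochberg step-up adjusted q-values
#'
#' Step-up false discovery rate adjustment:
#' `q(i) = min_{j >= i} p(j) * m / j` over ascending-sorted p-values, mapped
#' back to the input order and capped at 1.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.04, 0.03, 0.005))
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  m <- length(p_values)
  if (m == 0L) return(numeric(0))
  o <- order(p_values)
  q_sorted <- p_values[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

#' Pearson correlation with two-tailed p-value
#'
#' Product-moment correlation; the p-value comes from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors (n >= 3, nonzero variance).
#' @return One-row tibble: `r`, `p`, `n`.
#' @export
pearson_age_corr <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) abort("Need at least 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble::tibble(r = NA_real_, p = NA_real_, n = length(x),
                          flag = "zero_variance"))
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x),
                 flag = NA_character_)
}

#' Hemispheric laterality analysis
#'
#' Laterality index per subject, LI = (Right - Left) / (Right + Left); a
#' Shapiro-Wilk gate selects a one-sample t-test or Wilcoxon signed-rank
#' test of the LI distribution against zero. Effect size is Cohen's
#' dz = mean(LI) / sd(LI). Subjects with Right + Left = 0 are excluded and
#' counted.
#'
#' @param right,left Numeric vectors, paired by subject.
#' @return One-row tibble with `mean_li`, `sd_li`, CI, `p`, `effect_size`,
#'   `n_excluded`.
#' @export
laterality <- function(right, left) {
  if (length(right) != length(left)) abort("Paired vectors required.")
  tot <- right + left
  excl <- tot == 0 | !is.finite(tot)
  li <- (right[!excl] - left[!excl]) / tot[!excl]
  n <- length(li)
  if (n == 0L) abort("No usable subjects for the laterality index.")
  if (all(li == 0)) {
    return(tibble::tibble(mean_li = 0, sd_li = 0, ci_low = 0, ci_high = 0,
                          test = "one_sample_t", statistic = 0, p = 1,
                          effect_size = 0, n = n,
                          n_excluded = sum(excl), flag = "all_zero"))
  }
  dz <- if (sd(li) > 0) mean(li) / sd(li) else NA_real_
  if (is_normal(li)) {
    tt <- t.test(li, mu = 0)
    tibble::tibble(mean_li = mean(li), sd_li = sd(li),
                   ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
                   test = "one_sample_t", statistic = unname(tt$statistic),
                   p = tt$p.value, effect_size = dz, n = n,
                   n_excluded = sum(excl), flag = NA_character_)
  } else {
    wt <- suppressWarnings(wilcox.test(li[li != 0], mu = 0, exact = FALSE))
    se <- sd(li) / sqrt(n)
    ci <- mean(li) + qt(c(0.025, 0.975), n - 1) * se
    tibble::tibble(mean_li = mean(li), sd_li = sd(li),
                   ci_low = ci[1], ci_high = ci[2],
                   test = "wilcoxon_signed_rank",
                   statistic = unname(wt$statistic), p = wt$p.value,
                   effect_size = dz, n = n, n_excluded = sum(excl),
                   flag = NA_character_)
  }
}

#' Intracranial-volume normalisation of regional volumes
#'
#' ICV = GM + WM + CSF; every volume is expressed as a percentage of ICV;
#' gray/whole-brain and white/whole-brain ratios use WB = GM + WM.
#'
#' @param gm,wm,csf Volumes in mL (vectorised over subjects).
#' @param regional Optional named list / tibble of further regional volumes.
#' @return Tibble with `icv`, `wb`, `<name>_picv` percentage columns, and
#'   the `gm_wb` / `wm_wb` ratios.
#' @examples
#' volumetrics(685.2, 493.9, 300.0)
#' @export
volumetrics <- function(gm, wm, csf, regional = NULL) {
  if (any(c(gm, wm, csf) < 0)) abort("Volumes must be nonnegative.")
  icv <- gm + wm + csf
  if (any(icv == 0)) abort("ICV must be positive.")
  wb <- gm + wm
  out <- tibble::tibble(icv = icv, wb = wb,
                        wb_picv = 100 * wb / icv,
                        gm_picv = 100 * gm / icv,
                        wm_picv = 100 * wm / icv,
                        csf_picv = 100 * csf / icv,
                        gm_wb = gm / wb, wm_wb = wm / wb)
  if (!is.null(regional)) {
    for (nm in names(regional)) {
      out[[paste0(nm, "_picv")]] <- 100 * regional[[nm]] / icv
    }
  }
  out
}

#' Pearson chi-square test on a 2x2 table
#'
#' No continuity correction; df = 1; two-sided p from the chi-square
#' distribution.
#'
#' @param counts 2x2 matrix of nonnegative integer counts with positive
#'   margins.
#' @return One-row tibble: `statistic`, `df`, `p`.
#' @examples
#' chi_square_2x2(matrix(c(11, 14, 4, 5), 2))
#' @export
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) abort("`counts` must be 2x2.")
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Counts must be nonnegative integers.")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("All margins must be positive.")
  }
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic), df = 1L,
                 p = unname(ct$p.value))
}
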
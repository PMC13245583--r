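#' Run the full cohort statistical battery
#'
#' For each metric family (OEF, CBF, CMRO2) across the 11 regions: young-vs-
#' old group comparisons with Benjamini-Hochberg correction within the
#' family; within-group paired region-versus-whole-brain comparisons (BH per
#' group and family); age regressions with sex and normalized brain volume
#' as covariates (BH on the age term per family); volumetric group
#' comparisons; laterality of hippocampus and amygdala metrics (plus
#' thalamus volumes); and the 2x2 sex-by-group chi-square.
#'
#' @param cohort A cohort tibble with both groups (see [simulate_cohort()]).
#' @param regions Region codes for the metric families.
#' @param family_size BH family size for the metric families; defaults to
#'   the number of regions.
#' @param fdr_q Nominal FDR level recorded in the report.
#' @return An `oxibold_stats_report`: list of tibbles `group_tests`,
#'   `paired_tests`, `regressions`, `volume_tests`, `laterality_tests`,
#'   `sex_test`, plus the options used. [tidy()] binds the test tables into
#'   one long tibble.
#' @examples
#' rep <- run_stats_battery(simulate_cohort(cohort_config(seed = 3)))
#' head(tidy(rep))
#' @export
run_stats_battery <- function(cohort, regions = cohort_regions(),
                              family_size = length(regions), fdr_q = 0.05) {
  stopifnot(is.data.frame(cohort))
  if (!all(c("young", "old") %in% cohort$group)) {
    abort("Cohort must contain both a 'young' and an 'old' group.")
  }
  metrics <- c("oef", "cbf", "cmro2")
  needed <- as.vector(outer(regions, metrics, paste, sep = "_"))
  miss <- setdiff(needed, names(cohort))
  if (length(miss)) {
    abort(sprintf("Cohort table lacks region column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  young <- cohort[cohort$group == "young", ]
  old <- cohort[cohort$group == "old", ]

  # --- group comparisons, BH within each metric family (m = family_size)
  group_tests <- purrr::map_dfr(metrics, function(met) {
    fam <- purrr::map_dfr(regions, function(reg) {
      col <- paste0(reg, "_", met)
      res <- compare_groups(young[[col]], old[[col]])
      dplyr::bind_cols(tibble::tibble(family = met, region = reg,
                                      mean_young = mean(young[[col]]),
                                      mean_old = mean(old[[col]])), res)
    })
    fam$q <- bh_adjust(fam$p)
    fam
  })

  # --- paired region vs whole brain per group, BH within group x family
  paired_regions <- setdiff(regions, "wb")
  paired_tests <- purrr::map_dfr(metrics, function(met) {
    purrr::map_dfr(c("young", "old"), function(grp) {
      g <- cohort[cohort$group == grp, ]
      fam <- purrr::map_dfr(paired_regions, function(reg) {
        res <- compare_region_to_global(g[[paste0(reg, "_", met)]],
                                        g[[paste0("wb_", met)]])
        dplyr::bind_cols(tibble::tibble(family = met, group = grp,
                                        region = reg), res)
      })
      fam$q <- bh_adjust(fam$p)
      fam
    })
  })

  # --- age regressions (full covariate model), BH on the age term
  regressions <- purrr::map_dfr(metrics, function(met) {
    fam <- purrr::map_dfr(regions, function(reg) {
      m <- fit_age_model(cohort, met, reg)
      age_row <- m$coefficients[m$coefficients$term == "age", ]
      tibble::tibble(family = met, region = reg,
                     coefficient = age_row$estimate,
                     std_error = age_row$std_error,
                     ci_low = age_row$ci_low, ci_high = age_row$ci_high,
                     std_beta = age_row$std_beta, p = age_row$p,
                     r_squared = m$r_squared)
    })
    fam$q <- bh_adjust(fam$p)
    fam
  })

  # --- volumetrics: %ICV-normalised group comparisons + composition ratios
  vol_regions <- intersect(c("wb", "gm", "wm", "hc", "ag", "thl"),
                           sub("_vol$", "", grep("_vol$", names(cohort),
                                                 value = TRUE)))
  icv <- cohort$gm_vol + cohort$wm_vol + cohort$csf_vol
  volume_tests <- purrr::map_dfr(vol_regions, function(reg) {
    v <- 100 * cohort[[paste0(reg, "_vol")]] / icv
    res <- compare_groups(v[cohort$group == "young"],
                          v[cohort$group == "old"])
    dplyr::bind_cols(tibble::tibble(family = "volume_picv", region = reg),
                     res)
  })
  wbv <- cohort$gm_vol + cohort$wm_vol
  ratios <- list(gm_wb = cohort$gm_vol / wbv, wm_wb = cohort$wm_vol / wbv)
  volume_tests <- dplyr::bind_rows(volume_tests,
    purrr::map_dfr(names(ratios), function(nm) {
      r <- ratios[[nm]]
      res <- compare_groups(r[cohort$group == "young"],
                            r[cohort$group == "old"])
      dplyr::bind_cols(tibble::tibble(family = "volume_ratio", region = nm),
                       res)
    }))
  volume_tests$q <- bh_adjust(volume_tests$p)

  # --- laterality: metrics for hc/ag, volumes for hc/ag/thl, per group
  lat_specs <- rbind(
    expand.grid(region = c("hc", "ag"), metric = metrics,
                stringsAsFactors = FALSE),
    expand.grid(region = c("hc", "ag", "thl"), metric = "vol",
                stringsAsFactors = FALSE))
  laterality_tests <- purrr::map_dfr(c("young", "old"), function(grp) {
    g <- cohort[cohort$group == grp, ]
    purrr::map_dfr(seq_len(nrow(lat_specs)), function(i) {
      reg <- lat_specs$region[i]; met <- lat_specs$metric[i]
      stem <- if (met == "vol") paste0(reg, "_vol") else paste0(reg, "_", met)
      rc <- paste0(stem, "_right"); lc <- paste0(stem, "_left")
      if (!all(c(rc, lc) %in% names(g))) return(NULL)
      res <- laterality(g[[rc]], g[[lc]])
      dplyr::bind_cols(tibble::tibble(family = met, group = grp,
                                      region = reg), res)
    })
  })

  # --- sex distribution across groups
  sex_counts <- table(factor(cohort$group, c("young", "old")),
                      factor(cohort$sex, c("M", "F")))
  sex_test <- if (all(rowSums(sex_counts) > 0) && all(colSums(sex_counts) > 0)) {
    chi_square_2x2(unclass(sex_counts))
  } else {
    tibble::tibble(statistic = NA_real_, df = 1L, p = NA_real_)
  }

  structure(
    list(group_tests = group_tests, paired_tests = paired_tests,
         regressions = regressions, volume_tests = volume_tests,
         laterality_tests = laterality_tests, sex_test = sex_test,
         sex_counts = sex_counts,
         options = list(regions = regions, family_size = family_size,
                        fdr_q = fdr_q,
                        n_young = nrow(young), n_old = nrow(old))),
    class = "oxibold_stats_report"
  )
}

#' @export
print.oxibold_stats_report <- function(x, ...) {
  o <- x$options
  cat(sprintf("<oxibold_stats_report> %d young vs %d old, %d regions, FDR q = %.2f\n",
              o$n_young, o$n_old, length(o$regions), o$fdr_q))
  sig <- dplyr::filter(x$group_tests, .data$q < o$fdr_q)
  cat(sprintf("  group tests: %d of %d BH-significant\n",
              nrow(sig), nrow(x$group_tests)))
  cat(sprintf("  sex chi-square: X2 = %.3f, p = %.3f\n",
              x$sex_test$statistic, x$sex_test$p))
  invisible(x)
}

#' Tidy a statistics report into one long table
#'
#' @param x An `oxibold_stats_report`.
#' @param ... Unused.
#' @return Long tibble with a `component` column identifying the test table
#'   each row came from.
#' @export
tidy.oxibold_stats_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$group_tests, component = "group", .before = 1),
    dplyr::mutate(x$paired_tests, component = "paired", .before = 1),
    dplyr::mutate(
      dplyr::rename(x$regressions, estimate = "coefficient"),
      component = "regression", .before = 1),
    dplyr::mutate(x$volume_tests, component = "volume", .before = 1),
    dplyr::mutate(x$laterality_tests, component = "laterality", .before = 1),
    dplyr::mutate(x$sex_test, component = "sex_chi_square", .before = 1)
  )
}

#' @export
glance.oxibold_stats_report <- function(x, ...) {
  o <- x$options
  tibble::tibble(
    n_young = o$n_young, n_old = o$n_old,
    n_group_tests = nrow(x$group_tests),
    n_group_significant = sum(x$group_tests$q < o$fdr_q),
    n_regressions = nrow(x$regressions),
    sex_chi2_p = x$sex_test$p)
}

#' Plot group differences from a statistics report
#'
#' Dot plot of mean group differences (young - old) per region, faceted by
#' metric family, with BH-significant tests highlighted.
#'
#' @param object An `oxibold_stats_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oxibold_stats_report <- function(object, ...) {
  df <- dplyr::mutate(object$group_tests,
                      significant = .data$q < object$options$fdr_q)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$region,
                                   color = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~family, scales = "free_x") +
    ggplot2::labs(x = "Mean difference (young - old)", y = NULL,
                  color = "BH significant") +
    ggplot2::theme_minimal()
}

#' Plot regional metrics against age
#'
#' Scatter of a metric versus age for a set of regions with per-region
#' least-squares lines, colored by age group.
#'
#' @param cohort A cohort tibble.
#' @param metric One of `"oef"`, `"cbf"`, `"cmro2"`.
#' @param regions Region codes to facet over.
#' @return A ggplot object.
#' @export
plot_age_trends <- function(cohort, metric = "oef",
                            regions = c("wb", "gm", "wm", "hc")) {
  cols <- paste0(regions, "_", metric)
  miss <- setdiff(cols, names(cohort))
  if (length(miss)) abort(sprintf("Missing columns: %s",
                                  paste(miss, collapse = ", ")))
  long <- tidyr::pivot_longer(
    dplyr::select(cohort, "age_years", "group", dplyr::all_of(cols)),
    dplyr::all_of(cols), names_to = "region", values_to = "value")
  long$region <- sub(paste0("_", metric, "$"), "", long$region)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$age_years, y = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$group), alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "black", linewidth = 0.4) +
    ggplot2::facet_wrap(~region, scales = "free_y") +
    ggplot2::labs(x = "Age (years)", y = toupper(metric)) +
    ggplot2::theme_minimal()
}
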
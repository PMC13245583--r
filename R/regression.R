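#' Multiple linear regression of a regional metric on age
#'
#' Ordinary least squares of the form
#' `metric = b0 + b1 * age + b2 * sex + b3 * normalized_volume`,
#' with sex coded male = 1 / female = 0 and the normalized volume the
#' whole-brain volume as a percentage of intracranial volume
#' (ICV = GM + WM + CSF). Standard errors use the unbiased residual
#' variance; 95% CIs come from the t distribution with the residual degrees
#' of freedom. Standardized coefficients rescale each slope by
#' `sd(x) / sd(y)`. Residual-normality (Shapiro-Wilk) and heteroscedasticity
#' (Breusch-Pagan) diagnostics are attached.
#'
#' @param cohort A cohort tibble (see [simulate_cohort()]).
#' @param metric `"oef"`, `"cbf"`, `"cmro2"`, or `"vol"` (ICV-normalised
#'   regional volume as the response).
#' @param region Region code, e.g. `"wb"`, `"hc"` (see [cohort_regions()]).
#' @param covariates Subset of `c("age", "sex", "norm_vol")`; the default is
#'   the full model. `"age"` alone gives the simple regression whose
#'   standardized slope equals the Pearson correlation.
#' @return An `age_model` object; use [tidy()] / [glance()] to extract
#'   coefficient and model-level summaries.
#' @examples
#' coh <- simulate_cohort(cohort_config(seed = 7))
#' tidy(fit_age_model(coh, "oef", "wb"))
#' @export
fit_age_model <- function(cohort, metric = c("oef", "cbf", "cmro2", "vol"),
                          region = "wb",
                          covariates = c("age", "sex", "norm_vol")) {
  metric <- match.arg(metric)
  covariates <- match.arg(covariates, several.ok = TRUE)
  need <- c("age_years", "sex", "gm_vol", "wm_vol", "csf_vol")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    abort(sprintf("Cohort table lacks column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  icv <- cohort$gm_vol + cohort$wm_vol + cohort$csf_vol
  y <- if (metric == "vol") {
    col <- paste0(region, "_vol")
    if (!col %in% names(cohort)) abort(sprintf("Missing column `%s`.", col))
    100 * cohort[[col]] / icv
  } else {
    col <- paste0(region, "_", metric)
    if (!col %in% names(cohort)) abort(sprintf("Missing column `%s`.", col))
    cohort[[col]]
  }
  df <- data.frame(
    y = y,
    age = cohort$age_years,
    sex = as.numeric(cohort$sex == "M"),
    norm_vol = 100 * (cohort$gm_vol + cohort$wm_vol) / icv
  )
  df <- df[, c("y", covariates), drop = FALSE]
  if (!all(complete.cases(df))) abort("Missing covariate or response values.")
  if (nrow(df) < length(covariates) + 2L) abort("Too few subjects to fit.")

  sds_x <- vapply(df[covariates], sd, numeric(1))
  if (any(sds_x == 0)) {
    abort(sprintf("Collinear (degenerate) design among covariates: %s",
                  paste(covariates[sds_x == 0], collapse = ", ")))
  }
  if (length(covariates) > 1L) {
    kn <- kappa(scale(as.matrix(df[covariates])), exact = TRUE)
    if (!is.finite(kn) || kn > 1e8) {
      abort(sprintf("Collinear design among covariates: %s",
                    paste(covariates, collapse = ", ")))
    }
  }

  form <- stats::as.formula(paste("y ~", paste(covariates, collapse = " + ")))
  fit <- lm(form, data = df)
  sm <- summary(fit)
  ci <- confint(fit)
  co <- sm$coefficients
  sds <- vapply(df[covariates], sd, numeric(1))
  std_beta <- c(NA_real_, co[-1, 1] * sds / sd(df$y))

  coefs <- tibble::tibble(
    term = rownames(co),
    estimate = unname(co[, 1]), std_error = unname(co[, 2]),
    ci_low = unname(ci[, 1]), ci_high = unname(ci[, 2]),
    statistic = unname(co[, 3]), p = unname(co[, 4]),
    std_beta = unname(std_beta)
  )
  res <- residuals(fit)
  shapiro_p <- if (length(res) >= 3 && sd(res) > 0) {
    tryCatch(shapiro.test(res)$p.value, error = function(e) NA_real_)
  } else NA_real_
  bp_p <- tryCatch(lmtest::bptest(fit)$p.value, error = function(e) NA_real_)

  structure(
    list(coefficients = coefs, r_squared = sm$r.squared,
         adj_r_squared = sm$adj.r.squared, sigma = sm$sigma,
         n = nrow(df), metric = metric, region = region,
         covariates = covariates,
         diagnostics = list(residual_normality_p = shapiro_p,
                            heteroscedasticity_p = unname(bp_p),
                            heteroscedastic = !is.na(bp_p) && bp_p < 0.05),
         lm = fit),
    class = "age_model"
  )
}

#' @export
print.age_model <- function(x, ...) {
  cat(sprintf("<age_model> %s ~ %s in region '%s' (n = %d, R^2 = %.3f)\n",
              x$metric, paste(x$covariates, collapse = " + "), x$region,
              x$n, x$r_squared))
  print(x$coefficients)
  invisible(x)
}

#' Tidy an age regression
#'
#' @param x An `age_model`.
#' @param ... Unused.
#' @return Tibble of per-term coefficients, SEs, CIs, p-values, and
#'   standardized coefficients.
#' @export
tidy.age_model <- function(x, ...) x$coefficients

#' Model-level summary of an age regression
#'
#' @param x An `age_model`.
#' @param ... Unused.
#' @return One-row tibble: R^2, adjusted R^2, residual sigma, n, and
#'   diagnostic p-values.
#' @export
glance.age_model <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, adj_r_squared = x$adj_r_squared,
                 sigma = x$sigma, n = x$n,
                 residual_normality_p = x$diagnostics$residual_normality_p,
                 heteroscedasticity_p = x$diagnostics$heteroscedasticity_p)
}

#' @export
autoplot.age_model <- function(object, ...) {
  df <- object$lm$model
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         color = "steelblue") +
    ggplot2::labs(x = "Age (years)",
                  y = sprintf("%s (%s)", toupper(object$metric),
                              object$region),
                  title = sprintf("%s vs age, region %s",
                                  toupper(object$metric), object$region)) +
    ggplot2::theme_minimal()
}
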
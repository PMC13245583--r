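#' Regions reported by the cohort simulator and statistics battery
#'
#' @return Character vector of the 11 region codes: whole brain, gray and
#'   white matter, medial temporal lobe, hippocampus, amygdala, frontal /
#'   parietal / occipital lobes, thalamus, striatum.
#' @export
cohort_regions <- function() {
  c("wb", "gm", "wm", "mtl", "hc", "ag", "fl", "pl", "thl", "occ", "str")
}

#' Default age-structured regional physiology for the cohort simulator
#'
#' Per-region anchors (group means of OEF in % and CBF in mL/100 g/min at the
#' group reference ages), within-group age slopes (%/year for OEF,
#' mL/100 g/min/year for CBF), and residual SDs, for younger (23-35 y) and
#' older (50-87 y) healthy adults.
#'
#' @return Tibble with columns `region`, `oef_young`, `oef_old`,
#'   `oef_slope`, `oef_sd_young`, `oef_sd_old`, `cbf_young`, `cbf_old`,
#'   `cbf_slope`, `cbf_sd_young`, `cbf_sd_old`.
#' @export
default_cohort_params <- function() {
  tibble::tribble(
    ~region, ~oef_young, ~oef_old, ~oef_slope, ~oef_sd_young, ~oef_sd_old,
             ~cbf_young, ~cbf_old, ~cbf_slope, ~cbf_sd_young, ~cbf_sd_old,
    "wb",  34.5, 40.2, 0.150, 4.6, 5.1, 48.3, 39.5, -0.207,  8.3, 10.3,
    "gm",  34.9, 40.3, 0.128, 4.2, 4.7, 57.1, 47.7, -0.250, 10.4, 12.9,
    "wm",  33.5, 39.5, 0.164, 5.0, 5.6, 30.3, 28.2, -0.051,  7.1,  8.0,
    "mtl", 32.2, 37.4, 0.141, 5.1, 5.9, 45.5, 37.0, -0.208,  9.2, 10.6,
    "hc",  29.1, 37.2, 0.222, 6.1, 7.0, 45.1, 37.0, -0.187, 11.5, 10.9,
    "ag",  27.9, 38.3, 0.285, 6.1, 8.6, 39.4, 36.9, -0.026,  8.9, 12.0,
    "fl",  34.7, 38.7, 0.089, 5.0, 5.2, 57.6, 44.3, -0.327, 11.3, 11.8,
    "pl",  38.2, 43.9, 0.149, 5.5, 5.1, 62.1, 46.3, -0.385, 11.3, 13.7,
    "thl", 32.5, 40.5, 0.211, 7.1, 6.4, 38.9, 31.8, -0.178,  8.1,  8.4,
    "occ", 35.1, 40.7, 0.162, 5.3, 6.3, 59.1, 45.1, -0.344, 11.1, 14.0,
    "str", 36.2, 42.7, 0.169, 5.5, 5.3, 36.0, 28.9, -0.159, 10.5,  7.5
  )
}

#' Default regional brain volumes for the cohort simulator
#'
#' Mean and SD of regional volumes (mL) per age group. Whole brain is defined
#' as GM + WM; CSF closes the intracranial volume. Laterality offsets are 0
#' by default (symmetric hemispheres).
#'
#' @return Tibble with columns `region`, `mean_young`, `sd_young`,
#'   `mean_old`, `sd_old`.
#' @export
default_volume_params <- function() {
  tibble::tribble(
    ~region, ~mean_young, ~sd_young, ~mean_old, ~sd_old,
    "gm",  685.2, 72.1, 586.6, 86.3,
    "wm",  493.9, 48.8, 457.9, 62.4,
    "csf", 270.0, 35.0, 330.0, 50.0,
    "hc",    8.6,  0.9,   7.1,  1.5,
    "ag",    3.0,  0.6,   2.7,  0.8,
    "thl",  19.9,  2.1,  17.6,  3.3
  )
}

#' Cohort simulator configuration
#'
#' Defines the generative model for a two-group aging cohort: group sizes,
#' uniform age ranges, sex mix, hematocrit, per-region OEF/CBF anchors and
#' age slopes, residual SDs, volumes, and hemispheric asymmetry offsets.
#'
#' Each subject's regional metric is drawn as
#' `anchor[group] + slope * (age - ref_age[group]) + N(0, sd[group])`, with
#' the group reference ages defaulting to the midpoints of the age ranges so
#' the group means match the anchors in expectation. CMRO2 is never drawn:
#' it is always computed from the subject's OEF, CBF, and hematocrit via
#' Fick's principle.
#'
#' @param n_young,n_old Group sizes (>= 0).
#' @param age_range_young,age_range_old Uniform age ranges in years
#'   (non-overlapping).
#' @param ref_age_young,ref_age_old Reference ages anchoring the group means;
#'   default = range midpoints.
#' @param p_male Probability of male sex.
#' @param hct_mean_young,hct_sd_young,hct_mean_old,hct_sd_old Hematocrit
#'   (fraction) mean/SD per group.
#' @param region_params See [default_cohort_params()].
#' @param volume_params See [default_volume_params()].
#' @param li_offset Named list of laterality offsets (right-vs-left relative
#'   asymmetry, equal to the expected laterality index) for regions with
#'   hemispheric values (`hc`, `ag`, `thl`); defaults to 0 (symmetric).
#' @param seed Integer seed used by [simulate_cohort()].
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_young = 15L, n_old = 19L,
                          age_range_young = c(23, 35),
                          age_range_old = c(50, 87),
                          ref_age_young = mean(age_range_young),
                          ref_age_old = mean(age_range_old),
                          p_male = 25 / 34,
                          hct_mean_young = 0.438, hct_sd_young = 0.035,
                          hct_mean_old = 0.434, hct_sd_old = 0.053,
                          region_params = default_cohort_params(),
                          volume_params = default_volume_params(),
                          li_offset = list(hc = 0, ag = 0, thl = 0),
                          seed = 1L) {
  if (n_young < 0 || n_old < 0) abort("Group sizes must be nonnegative.")
  if (max(age_range_young) > min(age_range_old)) {
    abort("Group age ranges must not overlap.")
  }
  sds <- unlist(region_params[grepl("_sd_", names(region_params))])
  if (any(sds < 0)) abort("Residual SDs must be nonnegative.")
  structure(
    list(n_young = as.integer(n_young), n_old = as.integer(n_old),
         age_range_young = age_range_young, age_range_old = age_range_old,
         ref_age_young = ref_age_young, ref_age_old = ref_age_old,
         p_male = p_male,
         hct_mean_young = hct_mean_young, hct_sd_young = hct_sd_young,
         hct_mean_old = hct_mean_old, hct_sd_old = hct_sd_old,
         region_params = region_params, volume_params = volume_params,
         li_offset = li_offset, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Simulate an aging cohort table
#'
#' Draws one row per subject with demographics, hematocrit, per-region OEF
#' (%), CBF (mL/100 g/min) and CMRO2 (umol/100 g/min, computed by Fick's
#' principle from the subject's own OEF, CBF and hematocrit), regional
#' volumes (mL), and left/right hemispheric values for hippocampus, amygdala
#' (metrics and volumes) and thalamus (volumes). Deterministic for a fixed
#' seed.
#'
#' @param cfg A [cohort_config()].
#' @param seed Optional override of `cfg$seed`.
#' @param constants [physics_constants()].
#' @return A tibble (`cohort_table`), one row per subject.
#' @examples
#' coh <- simulate_cohort(cohort_config(seed = 42))
#' dplyr::count(coh, group)
#' @export
simulate_cohort <- function(cfg = cohort_config(), seed = NULL,
                            constants = physics_constants()) {
  stopifnot(inherits(cfg, "cohort_config"))
  seed <- if (is.null(seed)) cfg$seed else as.integer(seed)
  withr::with_seed(seed, simulate_cohort_impl(cfg, constants))
}

simulate_cohort_impl <- function(cfg, constants) {
  n <- cfg$n_young + cfg$n_old
  group <- c(rep("young", cfg$n_young), rep("old", cfg$n_old))
  age <- c(runif(cfg$n_young, cfg$age_range_young[1], cfg$age_range_young[2]),
           runif(cfg$n_old, cfg$age_range_old[1], cfg$age_range_old[2]))
  sex <- ifelse(rbinom(n, 1, cfg$p_male) == 1, "M", "F")
  hct <- ifelse(group == "young",
                rnorm(n, cfg$hct_mean_young, cfg$hct_sd_young),
                rnorm(n, cfg$hct_mean_old, cfg$hct_sd_old))
  hct <- pmin(pmax(hct, 0.25), 0.60)

  ref <- ifelse(group == "young", cfg$ref_age_young, cfg$ref_age_old)
  out <- tibble::tibble(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    group = group, age_years = age, sex = sex, hct = hct
  )

  rp <- cfg$region_params
  for (i in seq_len(nrow(rp))) {
    reg <- rp$region[i]
    anchor_oef <- ifelse(group == "young", rp$oef_young[i], rp$oef_old[i])
    sd_oef <- ifelse(group == "young", rp$oef_sd_young[i], rp$oef_sd_old[i])
    anchor_cbf <- ifelse(group == "young", rp$cbf_young[i], rp$cbf_old[i])
    sd_cbf <- ifelse(group == "young", rp$cbf_sd_young[i], rp$cbf_sd_old[i])
    oef <- anchor_oef + rp$oef_slope[i] * (age - ref) + rnorm(n, 0, sd_oef)
    cbf <- anchor_cbf + rp$cbf_slope[i] * (age - ref) + rnorm(n, 0, sd_cbf)
    oef <- pmin(pmax(oef, 1), 95)
    cbf <- pmax(cbf, 1)
    cmro2 <- fick_cmro2(cbf, hct, oef / 100, constants)
    out[[paste0(reg, "_oef")]] <- oef
    out[[paste0(reg, "_cbf")]] <- cbf
    out[[paste0(reg, "_cmro2")]] <- cmro2
  }

  # hemispheric metrics for hippocampus and amygdala: symmetric split around
  # the bilateral value plus configured asymmetry and small independent noise
  for (reg in c("hc", "ag")) {
    d <- cfg$li_offset[[reg]] %||% 0
    for (met in c("oef", "cbf")) {
      v <- out[[paste0(reg, "_", met)]]
      jit <- rnorm(n, 0, 0.01 * v)
      out[[paste0(reg, "_", met, "_right")]] <- v * (1 + d) + jit
      out[[paste0(reg, "_", met, "_left")]] <- v * (1 - d) - jit
    }
    r <- out[[paste0(reg, "_cmro2")]]
    oef_r <- out[[paste0(reg, "_oef_right")]]
    oef_l <- out[[paste0(reg, "_oef_left")]]
    cbf_r <- out[[paste0(reg, "_cbf_right")]]
    cbf_l <- out[[paste0(reg, "_cbf_left")]]
    out[[paste0(reg, "_cmro2_right")]] <- fick_cmro2(cbf_r, hct, pmin(oef_r, 95) / 100)
    out[[paste0(reg, "_cmro2_left")]] <- fick_cmro2(cbf_l, hct, pmin(oef_l, 95) / 100)
  }

  vp <- cfg$volume_params
  for (i in seq_len(nrow(vp))) {
    reg <- vp$region[i]
    m <- ifelse(group == "young", vp$mean_young[i], vp$mean_old[i])
    s <- ifelse(group == "young", vp$sd_young[i], vp$sd_old[i])
    v <- pmax(rnorm(n, m, s), 0.1)
    out[[paste0(reg, "_vol")]] <- v
  }
  out$wb_vol <- out$gm_vol + out$wm_vol
  for (reg in c("hc", "ag", "thl")) {
    d <- cfg$li_offset[[reg]] %||% 0
    v <- out[[paste0(reg, "_vol")]]
    jit <- rnorm(n, 0, 0.01 * v)
    out[[paste0(reg, "_vol_right")]] <- v / 2 * (1 + d) + jit
    out[[paste0(reg, "_vol_left")]] <- v / 2 * (1 - d) - jit
  }

  class(out) <- c("cohort_table", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a cohort table as TSV
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @return `read_cohort` returns the tibble; `write_cohort` the path,
#'   invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  out <- tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                             stringsAsFactors = FALSE))
  class(out) <- c("cohort_table", class(out))
  out
}
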
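#' Region label codes used by the digital phantom
#'
#' Integer codes for the phantom label volume. Code 0 is background. Cortical
#' lobes (frontal, parietal, occipital) are subsets of gray matter; the
#' hippocampus and amygdala are subsets of the medial temporal lobe. The
#' helper [region_members()] expands a named ROI into the label codes it
#' comprises.
#'
#' @return Named integer vector of label codes.
#' @examples
#' phantom_labels()
#' @export
phantom_labels <- function() {
  c(background = 0L, gm = 1L, wm = 2L, mtl = 3L, hc = 4L, ag = 5L,
    thl = 6L, str = 7L, fl = 8L, pl = 9L, occ = 10L, csf = 11L)
}

#' @rdname phantom_labels
#' @param roi ROI name: one of `"wb"`, `"gm"`, `"wm"`, `"mtl"`, `"hc"`,
#'   `"ag"`, `"thl"`, `"str"`, `"fl"`, `"pl"`, `"occ"`, `"csf"`.
#' @export
region_members <- function(roi) {
  lab <- phantom_labels()
  switch(roi,
    wb  = unname(lab[c("gm", "wm", "mtl", "hc", "ag", "thl", "str",
                       "fl", "pl", "occ")]),
    gm  = unname(lab[c("gm", "fl", "pl", "occ")]),
    wm  = unname(lab["wm"]),
    mtl = unname(lab[c("mtl", "hc", "ag")]),
    hc  = unname(lab["hc"]),
    ag  = unname(lab["ag"]),
    thl = unname(lab["thl"]),
    str = unname(lab["str"]),
    fl  = unname(lab["fl"]),
    pl  = unname(lab["pl"]),
    occ = unname(lab["occ"]),
    csf = unname(lab["csf"]),
    abort(sprintf("Unknown ROI name '%s'.", roi))
  )
}

#' Default per-region phantom parameters
#'
#' Piecewise-constant physiological parameters per phantom region. OEF and
#' CBF anchors follow group means reported for healthy younger / older
#' adults; relaxation rates, blood volumes and tissue susceptibilities are
#' physiologically plausible 3 T values (iron-rich deep gray structures get
#' larger non-heme R2' and susceptibility).
#'
#' @param group `"young"` or `"old"` selects the OEF/CBF anchor set.
#' @param constants [physics_constants()] (used to convert OEF to Yv).
#' @return A tibble with one row per region: `name`, `label`, `yv`, `dbv`,
#'   `r2`, `r2p_nh`, `chi_nb`, `cbvv`, `cbva`, `cbf`.
#' @examples
#' default_region_params("young")
#' @export
default_region_params <- function(group = c("young", "old"),
                                  constants = physics_constants()) {
  group <- match.arg(group)
  lab <- phantom_labels()
  # OEF (%) and CBF (mL/100 g/min) group anchors by region
  oef <- if (group == "young") {
    c(gm = 34.9, wm = 33.5, mtl = 32.2, hc = 29.1, ag = 27.9, thl = 32.5,
      str = 36.2, fl = 34.7, pl = 38.2, occ = 35.1)
  } else {
    c(gm = 40.3, wm = 39.5, mtl = 37.4, hc = 37.2, ag = 38.3, thl = 40.5,
      str = 42.7, fl = 38.7, pl = 43.9, occ = 40.7)
  }
  cbf <- if (group == "young") {
    c(gm = 57.1, wm = 30.3, mtl = 45.5, hc = 45.1, ag = 39.4, thl = 38.9,
      str = 36.0, fl = 57.6, pl = 62.1, occ = 59.1)
  } else {
    c(gm = 47.7, wm = 28.2, mtl = 37.0, hc = 37.0, ag = 36.9, thl = 31.8,
      str = 28.9, fl = 44.3, pl = 46.3, occ = 45.1)
  }
  r2     <- c(gm = 14, wm = 17, mtl = 15, hc = 15, ag = 15, thl = 18,
              str = 19, fl = 14, pl = 14, occ = 14.5)
  r2p_nh <- c(gm = 0.8, wm = 1.5, mtl = 1.0, hc = 1.0, ag = 1.0, thl = 2.0,
              str = 3.0, fl = 0.8, pl = 0.8, occ = 0.9)
  chi_nb <- c(gm = 0.01, wm = -0.03, mtl = 0.005, hc = 0.005, ag = 0.005,
              thl = 0.02, str = 0.05, fl = 0.01, pl = 0.01, occ = 0.01)
  cbvv   <- c(gm = 0.030, wm = 0.020, mtl = 0.028, hc = 0.028, ag = 0.028,
              thl = 0.030, str = 0.030, fl = 0.030, pl = 0.030, occ = 0.032)
  regions <- names(oef)
  out <- tibble::tibble(
    name = regions,
    label = unname(lab[regions]),
    yv = unname(yv_from_oef(oef[regions] / 100, constants)),
    dbv = unname(cbvv[regions]),
    r2 = unname(r2[regions]),
    r2p_nh = unname(r2p_nh[regions]),
    chi_nb = unname(chi_nb[regions]),
    cbvv = unname(cbvv[regions]),
    cbva = 0.01,
    cbf = unname(cbf[regions])
  )
  # CSF: long T2, no blood
  dplyr::bind_rows(out, tibble::tibble(
    name = "csf", label = unname(lab["csf"]), yv = constants$sao2, dbv = 0,
    r2 = 2, r2p_nh = 0.2, chi_nb = 0, cbvv = 0, cbva = 0, cbf = 0))
}

#' Build a digital phantom with nested geometric regions
#'
#' Constructs a ground-truth parameter volume on a rectangular grid. Geometry
#' is synthetic, not anatomical: an ellipsoidal "head" with an outer CSF
#' shell, a cortical gray matter shell partitioned into frontal / parietal /
#' occipital sectors, a white matter core, and bilateral subcortical boxes
#' (thalamus, striatum, and a medial temporal block containing hippocampus
#' and amygdala). Only regions present in `region_params` are constructed.
#' Parameter maps are piecewise constant per region, with optional Gaussian
#' within-region jitter.
#'
#' A smooth quadratic background field (ppm) is attached as the macroscopic
#' field offset truth.
#'
#' @param dim Grid dimensions, length-3 integer, each >= 8.
#' @param voxel_size Voxel size in mm, length-3 positive.
#' @param region_params Per-region parameter table, see
#'   [default_region_params()]. Every region the geometry generates must have
#'   a row; a missing row is a configuration error naming the label.
#' @param hct Subject hematocrit (scalar fraction).
#' @param jitter_sd Named numeric vector of within-region Gaussian jitter SDs
#'   for any of `yv`, `dbv`, `r2`, `r2p_nh`, `chi_nb`, `cbvv`, `cbf` (in the
#'   parameter's own units). Default: no jitter.
#' @param db0_amplitude_ppm Amplitude of the quadratic background field, ppm.
#' @param seed Integer seed controlling the jitter draw (labels are
#'   deterministic regardless).
#' @param constants [physics_constants()].
#'
#' @return A `phantom_truth` object: integer `labels` array, list `maps` of
#'   parameter arrays (NA outside tissue), `db0_ppm` array, scalars `hct`,
#'   `b0`, `voxel_size`, and the `region_params` used.
#' @examples
#' ph <- make_digital_phantom(dim = c(16, 16, 8))
#' table(ph$labels)
#' @export
make_digital_phantom <- function(dim = c(32, 32, 16),
                                 voxel_size = c(1.5, 1.5, 3),
                                 region_params = default_region_params(),
                                 hct = 0.44,
                                 jitter_sd = NULL,
                                 db0_amplitude_ppm = 0.02,
                                 seed = NULL,
                                 constants = physics_constants()) {
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 8L)) {
    abort("`dim` must be three integers, each >= 8.")
  }
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    abort("`voxel_size` must be three positive values (mm).")
  }
  stopifnot(is.data.frame(region_params),
            all(c("name", "label") %in% names(region_params)))

  lab <- phantom_labels()
  have <- region_params$name
  unknown <- setdiff(have, names(lab))
  if (length(unknown)) {
    abort(sprintf("No geometry/label defined for region(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  mismatch <- region_params$label != lab[have]
  if (any(mismatch)) {
    abort(sprintf("Parameter row label code(s) do not match their region: %s",
                  paste(region_params$label[mismatch], collapse = ", ")))
  }
  labels <- array(0L, dim)

  # normalised coordinates in [-1, 1]
  cx <- (seq_len(dim[1]) - (dim[1] + 1) / 2) / (dim[1] / 2)
  cy <- (seq_len(dim[2]) - (dim[2] + 1) / 2) / (dim[2] / 2)
  cz <- (seq_len(dim[3]) - (dim[3] + 1) / 2) / (dim[3] / 2)
  X <- array(rep(cx, times = dim[2] * dim[3]), dim)
  Y <- array(rep(rep(cy, each = dim[1]), times = dim[3]), dim)
  Z <- array(rep(cz, each = dim[1] * dim[2]), dim)
  rho <- sqrt((X / 0.97)^2 + (Y / 0.97)^2 + (Z / 0.97)^2)

  assign_region <- function(labels, name, sel) {
    if (!name %in% have) return(labels)
    labels[sel] <- lab[[name]]
    labels
  }
  labels <- assign_region(labels, "csf", rho <= 1)
  labels <- assign_region(labels, "gm", rho <= 0.88)
  shell <- rho <= 0.88 & rho > 0.60
  labels <- assign_region(labels, "fl", shell & Y > 0.25)
  labels <- assign_region(labels, "occ", shell & Y < -0.55)
  labels <- assign_region(labels, "pl", shell & Y <= 0.25 & Y >= -0.55 & Z > 0.25)
  labels <- assign_region(labels, "wm", rho <= 0.60)
  core <- rho <= 0.60
  labels <- assign_region(labels, "thl",
                          core & abs(X) <= 0.18 & abs(Y) <= 0.14 & abs(Z) <= 0.25)
  labels <- assign_region(labels, "str",
                          core & abs(X) >= 0.24 & abs(X) <= 0.42 &
                            Y >= 0.02 & Y <= 0.30 & abs(Z) <= 0.25)
  mtl_box <- core & abs(X) >= 0.20 & abs(X) <= 0.55 &
    Y <= -0.05 & Y >= -0.50 & Z <= -0.05 & Z >= -0.55
  labels <- assign_region(labels, "mtl", mtl_box)
  labels <- assign_region(labels, "hc",
                          mtl_box & abs(X) >= 0.24 & abs(X) <= 0.48 &
                            Y <= -0.22 & Y >= -0.46)
  labels <- assign_region(labels, "ag",
                          mtl_box & abs(X) >= 0.24 & abs(X) <= 0.48 &
                            Y <= -0.08 & Y > -0.20)

  present <- sort(unique(as.integer(labels)))
  present <- present[present != 0L]
  missing <- setdiff(present, region_params$label)
  if (length(missing)) {
    abort(sprintf("No parameter row for generated label(s): %s",
                  paste(missing, collapse = ", ")))
  }
  empty <- setdiff(region_params$label, present)
  if (length(empty)) {
    warn(sprintf("Requested region label(s) produced no voxels at this grid size: %s",
                 paste(empty, collapse = ", ")))
  }

  par_names <- c("yv", "dbv", "r2", "r2p_nh", "chi_nb", "cbvv", "cbva", "cbf")
  maps <- lapply(par_names, function(p) array(NA_real_, dim))
  names(maps) <- par_names
  for (i in seq_len(nrow(region_params))) {
    sel <- labels == region_params$label[i]
    if (!any(sel)) next
    for (p in par_names) maps[[p]][sel] <- region_params[[p]][i]
  }

  if (!is.null(jitter_sd) && any(jitter_sd > 0)) {
    draw <- function() {
      for (p in names(jitter_sd)) {
        if (!p %in% par_names || jitter_sd[[p]] <= 0) next
        sel <- !is.na(maps[[p]])
        maps[[p]][sel] <- maps[[p]][sel] + rnorm(sum(sel), 0, jitter_sd[[p]])
        if (p %in% c("yv", "dbv", "cbvv", "cbva")) {
          maps[[p]][sel] <- pmin(pmax(maps[[p]][sel], 0),
                                 if (p == "yv") constants$sao2 else 0.2)
        }
        if (p %in% c("r2", "r2p_nh", "cbf")) {
          maps[[p]][sel] <- pmax(maps[[p]][sel], 0)
        }
      }
      maps
    }
    maps <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  }

  # smooth quadratic background field, deterministic shape
  db0 <- db0_amplitude_ppm * (0.6 * X + 0.3 * Y - 0.2 * Z +
                                0.5 * X^2 - 0.4 * Y * Z)

  structure(
    list(labels = labels, maps = maps, db0_ppm = db0, hct = hct,
         b0 = constants$b0, voxel_size = voxel_size,
         region_params = region_params, dim = dim),
    class = "phantom_truth"
  )
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d x %d x %d grid, voxel %.1f x %.1f x %.1f mm\n",
              x$dim[1], x$dim[2], x$dim[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  tab <- table(x$labels)
  lab <- phantom_labels()
  nm <- names(lab)[match(as.integer(names(tab)), lab)]
  cat("  labels:", paste(sprintf("%s=%d", nm, tab), collapse = ", "), "\n")
  invisible(x)
}

#' Ground-truth OEF map of a phantom
#'
#' @param truth A `phantom_truth`.
#' @param constants [physics_constants()].
#' @return Array of OEF fractions (NA outside tissue).
#' @export
phantom_oef <- function(truth, constants = physics_constants()) {
  stopifnot(inherits(truth, "phantom_truth"))
  (constants$sao2 - truth$maps$yv) / constants$sao2
}
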
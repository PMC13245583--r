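#' Read and write volumes as NIfTI-1
#'
#' Thin wrappers over RNifti preserving voxel dimensions and affine.
#' `write_volume` stores data as float32 by default (sufficient for all
#' parametric maps; pass `datatype = "double"` for lossless intermediates).
#'
#' @param vol Numeric 3-D array (or `niftiImage`).
#' @param path File path (`.nii` or `.nii.gz`).
#' @param voxel_size Voxel size in mm (length 3).
#' @param datatype NIfTI on-disk datatype.
#' @return `read_volume` returns a `niftiImage` (an array with NIfTI
#'   metadata attached); `write_volume` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' write_volume(array(rnorm(8^3), c(8, 8, 8)), f)
#' v <- read_volume(f)
#' dim(v)
#' @export
write_volume <- function(vol, path, voxel_size = c(1.5, 1.5, 3),
                         datatype = "float") {
  dir <- dirname(path)
  if (!dir.exists(dir)) abort(sprintf("Directory does not exist: %s", dir))
  img <- RNifti::asNifti(vol)
  if (!is.null(voxel_size)) {
    RNifti::pixdim(img) <- voxel_size[seq_len(min(3L, length(dim(vol))))]
  }
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  out <- tryCatch(RNifti::readNifti(path),
                  error = function(e) {
                    abort(sprintf("Malformed NIfTI file %s: %s", path,
                                  conditionMessage(e)))
                  })
  out
}

#' Pipeline configuration
#'
#' Assembles (and validates) the resolved configuration of an end-to-end
#' run: physics constants, acquisition timing, phantom geometry, cohort
#' generation, fit weights, statistics options, and the master seed. Unknown
#' keys in any section are rejected. [read_pipeline_config()] loads a YAML
#' file with the same section structure; [write_pipeline_config()] freezes
#' the resolved configuration next to a run's outputs.
#'
#' @param physics,acquisition,phantom,cohort,fit,stats Named lists of
#'   overrides for each section (defaults: package defaults).
#' @param seed Master seed (integer).
#' @param noise_sd AUSFIDE per-channel noise SD (signal units).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(physics = list(), acquisition = list(),
                            phantom = list(), cohort = list(),
                            fit = list(), stats = list(), seed = 1L,
                            noise_sd = 0) {
  check_keys <- function(x, allowed, section) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      abort(sprintf("Unknown key(s) in [%s]: %s", section,
                    paste(bad, collapse = ", ")))
    }
    x
  }
  check_keys(physics, names(formals(physics_constants)), "physics")
  check_keys(acquisition, names(formals(acquisition_config)), "acquisition")
  check_keys(phantom, c("dim", "voxel_size", "group", "hct",
                        "db0_amplitude_ppm", "jitter_sd"), "phantom")
  check_keys(cohort, setdiff(names(formals(cohort_config)),
                             c("region_params", "volume_params")), "cohort")
  check_keys(fit, names(formals(fit_weights)), "fit")
  check_keys(stats, c("family_size", "fdr_q"), "stats")
  if (!is.numeric(seed) || length(seed) != 1L) abort("`seed` must be scalar.")
  if (!is.null(phantom$hct) &&
      (phantom$hct <= 0 || phantom$hct >= 1)) {
    abort("phantom hct must lie in (0, 1).")
  }
  structure(list(physics = physics, acquisition = acquisition,
                 phantom = phantom, cohort = cohort, fit = fit,
                 stats = stats, seed = as.integer(seed),
                 noise_sd = noise_sd),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  raw <- yaml::read_yaml(path)
  allowed <- c("physics", "acquisition", "phantom", "cohort", "fit",
               "stats", "seed", "noise_sd")
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) {
    abort(sprintf("Unknown top-level config key(s): %s",
                  paste(bad, collapse = ", ")))
  }
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
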
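# File formats: NIfTI volumes (via RNifti), YAML pool/scheme configs, and
# schedule-consistency checks.

#' Read a NIfTI volume checked against a schedule
#'
#' @param path NIfTI-1 file path.
#' @param schedule Optional [acq_schedule()]; if given, the number of
#'   volumes in the 4D stack must equal the number of schedule rows.
#' @return An `niftiImage` (array-like) as returned by [RNifti::readNifti()].
#' @export
read_volume <- function(path, schedule = NULL) {
  img <- RNifti::readNifti(path)
  if (!is.null(schedule)) {
    nv <- if (length(dim(img)) >= 4L) dim(img)[4L] else 1L
    if (nv != nrow(schedule))
      stop("schedule/volume count mismatch: schedule has ", nrow(schedule),
           " rows but '", path, "' has ", nv, " volumes")
  }
  img
}

#' Write an array as NIfTI
#'
#' @param data Numeric array (2D-4D).
#' @param path Output path (`.nii` / `.nii.gz`).
#' @param template Optional image to copy header/affine from.
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, path, template = NULL) {
  img <- if (is.null(template)) RNifti::asNifti(data)
         else RNifti::asNifti(data, reference = template)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read a pool system as a YAML configuration
#'
#' @param system A [pool_system()].
#' @param path YAML file path.
#' @return `read_pool_config()` returns a [pool_system()].
#' @export
write_pool_config <- function(system, path) {
  cfg <- list(center_freq_mhz = system$center_freq_mhz,
              pools = lapply(system$pools, function(p)
                list(name = p$name, shift_ppm = p$shift_ppm, t1 = p$t1,
                     t2 = p$t2, m0r = p$m0r, k_to_water = p$k,
                     klass = p$klass,
                     lineshape = if (is.na(p$lineshape)) NULL else p$lineshape)))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_pool_config
#' @export
read_pool_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  pools <- lapply(cfg$pools, function(p)
    pool(p$name, p$shift_ppm, p$t1, p$t2, p$m0r, p$k_to_water,
         klass = p$klass,
         lineshape = if (is.null(p$lineshape)) "super_lorentzian" else p$lineshape))
  pool_system(pools, center_freq_mhz = cfg$center_freq_mhz)
}
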
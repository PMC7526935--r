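FORMAT_VERSION <- "1"

#' Write / read a fan-beam scan as HDF5
#'
#' Layout (format_version 1): datasets `values` (views x channels),
#' `view_angles`, `view_times`; group attributes for every geometry field
#' and the ECG parameters.
#'
#' @param sino A `fan_sinogram`.
#' @param path Output `.h5` path (overwritten).
#' @return `path`, invisibly (`write_scan`); a `fan_sinogram` (`read_scan`).
#' @export
write_scan <- function(sino, path) {
  stopifnot(inherits(sino, "fan_sinogram"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(sino$values, path, "values")
  rhdf5::h5write(sino$timeline$view_angles, path, "view_angles")
  rhdf5::h5write(sino$timeline$view_times, path, "view_times")
  g <- sino$geometry
  meta <- list(source_to_iso = g$source_to_iso,
               source_to_detector = g$source_to_detector,
               n_channels = g$n_channels, fan_angle = g$fan_angle,
               views_per_rotation = g$views_per_rotation,
               rotation_time = g$rotation_time,
               heart_rate = sino$ecg$heart_rate, t0_rpeak = sino$ecg$t0_rpeak)
  rhdf5::h5createGroup(path, "meta")
  for (nm in names(meta)) rhdf5::h5write(meta[[nm]], path, paste0("meta/", nm))
  rhdf5::h5write(FORMAT_VERSION, path, "format_version")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_scan
#' @export
read_scan <- function(path) {
  meta <- lapply(rhdf5::h5read(path, "meta"), as.numeric)
  g <- system_geometry(source_to_iso = meta[["source_to_iso"]],
                       source_to_detector = meta[["source_to_detector"]],
                       n_channels = meta[["n_channels"]],
                       fan_angle = meta[["fan_angle"]],
                       views_per_rotation = meta[["views_per_rotation"]],
                       rotation_time = meta[["rotation_time"]])
  angles <- as.numeric(rhdf5::h5read(path, "view_angles"))
  times <- as.numeric(rhdf5::h5read(path, "view_times"))
  tl <- structure(list(view_angles = angles, view_times = times,
                       d_angle = angles[2] - angles[1],
                       d_time = times[2] - times[1],
                       n_views = length(angles)),
                  class = "scan_timeline")
  vals <- as.matrix(rhdf5::h5read(path, "values"))
  rhdf5::h5closeAll()
  structure(list(values = vals, geometry = g, timeline = tl,
                 ecg = ecg_model(meta[["heart_rate"]], meta[["t0_rpeak"]])),
            class = "fan_sinogram")
}

#' Write / read a motion vector field as HDF5
#'
#' Datasets: `controls` (gx x gy x 2, mm), `spacing_mm`, `origin_mm`,
#' `t_start`, `t_end`, `displacement_cap`.
#'
#' @param mvf A [motion_vector_field()].
#' @param path Output `.h5` path.
#' @return `path` invisibly (`write_mvf`); a `motion_vector_field`
#'   (`read_mvf`).
#' @export
write_mvf <- function(mvf, path) {
  stopifnot(inherits(mvf, "motion_vector_field"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(mvf$controls, path, "controls")
  rhdf5::h5write(mvf$spacing, path, "spacing_mm")
  rhdf5::h5write(mvf$origin, path, "origin_mm")
  rhdf5::h5write(c(mvf$t_start, mvf$t_end), path, "t_range")
  rhdf5::h5write(mvf$displacement_cap, path, "displacement_cap")
  rhdf5::h5write(FORMAT_VERSION, path, "format_version")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_mvf
#' @export
read_mvf <- function(path) {
  tr <- as.numeric(rhdf5::h5read(path, "t_range"))
  out <- motion_vector_field(
    controls = rhdf5::h5read(path, "controls"),
    spacing = as.numeric(rhdf5::h5read(path, "spacing_mm")),
    origin = as.numeric(rhdf5::h5read(path, "origin_mm")),
    t_start = tr[1], t_end = tr[2],
    displacement_cap = as.numeric(rhdf5::h5read(path, "displacement_cap")))
  rhdf5::h5closeAll()
  out
}

#' Write / read a reconstruction image as NIfTI-1
#'
#' Values are stored in Hounsfield units with the pixel size in the header.
#'
#' @param img A [recon_image()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @param mu_water Water attenuation used for the HU conversion on read.
#' @return `path` invisibly (`write_image_nifti`); a [recon_image()]
#'   (`read_image_nifti`).
#' @export
write_image_nifti <- function(img, path) {
  stopifnot(inherits(img, "recon_image"))
  arr <- array(mu_to_hu(img$values, img$mu_water),
               dim = c(img$grid$n, img$grid$n, 1))
  attr(arr, "pixdim") <- rep(img$grid$pixel_size, 3)
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' @rdname write_image_nifti
#' @export
read_image_nifti <- function(path, mu_water = 0.02) {
  nii <- RNifti::readNifti(path)
  px <- RNifti::pixdim(nii)[1]
  arr <- as.array(nii)
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  vals <- matrix(as.numeric(arr), nrow(arr), ncol(arr))
  recon_image(hu_to_mu(vals, mu_water), recon_grid(nrow(vals), px),
              mu_water = mu_water)
}
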
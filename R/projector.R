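#' Fan-beam system geometry
#'
#' Third-generation CT geometry with an equiangular (curved) detector. The
#' tube angle `beta` is measured from the +y axis; the source sits at
#' `source_to_iso * (-sin(beta), cos(beta))`. An equiangular channel `k`
#' (0-based) views the in-fan angle `gamma_k = (k - (n_channels-1)/2) *
#' fan_angle/(n_channels-1)`; the ray `(beta, gamma)` is the line with normal
#' angle `theta = beta + gamma` and signed distance `s = source_to_iso *
#' sin(gamma)` from the isocenter, which is what makes fan-to-parallel
#' rebinning a pure resampling.
#'
#' @param source_to_iso Source-isocenter distance, mm.
#' @param source_to_detector Source-detector distance, mm.
#' @param n_channels Number of detector channels.
#' @param fan_angle Full fan aperture, degrees (default 52).
#' @param views_per_rotation Views per full gantry rotation.
#' @param rotation_time Gantry rotation time, seconds (default 0.25).
#' @return An object of class `system_geometry`.
#' @export
system_geometry <- function(source_to_iso = 570, source_to_detector = 1040,
                            n_channels = 736, fan_angle = 52,
                            views_per_rotation = 720, rotation_time = 0.25) {
  stopifnot(source_to_detector > source_to_iso, source_to_iso > 0,
            fan_angle > 0, fan_angle < 90, n_channels >= 2,
            views_per_rotation >= 4, rotation_time > 0)
  structure(list(source_to_iso = source_to_iso,
                 source_to_detector = source_to_detector,
                 n_channels = as.integer(n_channels),
                 fan_angle = fan_angle,
                 fan_angle_rad = fan_angle * pi / 180,
                 views_per_rotation = as.integer(views_per_rotation),
                 rotation_time = rotation_time),
            class = "system_geometry")
}

#' Scan field of view radius
#'
#' Largest `|s|` measurable by the fan: `source_to_iso * sin(fan_angle/2)`.
#'
#' @param geometry A [system_geometry()].
#' @return Radius in mm.
#' @export
scan_fov_radius <- function(geometry) {
  geometry$source_to_iso * sin(geometry$fan_angle_rad / 2)
}

#' Scan timeline
#'
#' Uniform rotation: view `v` (0-based) has tube angle `start_angle +
#' v * 2*pi/views_per_rotation` and time `start_time + v *
#' rotation_time/views_per_rotation`.
#'
#' @param geometry A [system_geometry()].
#' @param n_rotations Number of gantry rotations to cover.
#' @param start_angle First tube angle, radians.
#' @param start_time First view time, seconds.
#' @return An object of class `scan_timeline` with `view_angles`,
#'   `view_times`, `d_angle`, `d_time`.
#' @export
scan_timeline <- function(geometry, n_rotations = 2, start_angle = 0,
                          start_time = 0) {
  nv <- ceiling(n_rotations * geometry$views_per_rotation)
  d_angle <- 2 * pi / geometry$views_per_rotation
  d_time <- geometry$rotation_time / geometry$views_per_rotation
  structure(list(view_angles = start_angle + (0:(nv - 1)) * d_angle,
                 view_times = start_time + (0:(nv - 1)) * d_time,
                 d_angle = d_angle, d_time = d_time, n_views = nv),
            class = "scan_timeline")
}

#' Ray of a detector channel
#'
#' @param geometry A [system_geometry()].
#' @param view_angle Tube angle, radians.
#' @param channel 0-based channel index.
#' @return List with `point` (source position, mm), `dir` (unit direction),
#'   `gamma` (in-fan angle, radians), `s` (signed ray distance, mm),
#'   `theta` (ray normal angle, radians).
#' @export
ray_for <- function(geometry, view_angle, channel) {
  nc <- geometry$n_channels
  if (any(channel < 0 | channel > nc - 1)) stop("channel out of range")
  dg <- geometry$fan_angle_rad / (nc - 1)
  gamma <- (channel - (nc - 1) / 2) * dg
  theta <- view_angle + gamma
  src <- geometry$source_to_iso * c(-sin(view_angle), cos(view_angle))
  list(point = src, dir = c(sin(theta), -cos(theta)), gamma = gamma,
       s = geometry$source_to_iso * sin(gamma), theta = theta)
}

# chord length of rays (qx,qy)+(t*ux,t*uy) through an ellipse, vectorised
# over rays; directions must be unit length
chord_ellipse <- function(center, semi, tilt, qx, qy, ux, uy) {
  ct <- cos(tilt); st <- sin(tilt)
  dx <- qx - center[1]; dy <- qy - center[2]
  # into the unit-disk frame
  px <- (ct * dx + st * dy) / semi[1]
  py <- (-st * dx + ct * dy) / semi[2]
  vx <- (ct * ux + st * uy) / semi[1]
  vy <- (-st * ux + ct * uy) / semi[2]
  a <- vx * vx + vy * vy
  b <- 2 * (px * vx + py * vy)
  cc <- px * px + py * py - 1
  disc <- b * b - 4 * a * cc
  len <- numeric(length(qx + ux))
  hit <- disc > 0
  len[hit] <- sqrt(disc[hit]) / a[hit]
  len
}

# line integral of a frozen phantom (additive decomposition from snapshot())
# along rays; vectorised over rays
frozen_line_integral <- function(frozen, qx, qy, ux, uy) {
  p <- 0
  for (fp in frozen) {
    ch <- chord_ellipse(fp$center, fp$semi_axes, fp$tilt, qx, qy, ux, uy)
    if (fp$shape == "annulus")
      ch <- ch - chord_ellipse(fp$center, fp$inner_semi_axes, fp$tilt,
                               qx, qy, ux, uy)
    p <- p + fp$mu_add * ch
    if (fp$shape == "notched_rod")
      p <- p + (fp$notch_mu - fp$mu) *
        chord_ellipse(fp$notch_center, fp$notch_semi_axes, 0, qx, qy, ux, uy)
  }
  p
}

#' Line integral of a single frozen primitive along a ray
#'
#' Analytic chord length times attenuation: the projector's elementary
#' oracle. Painting-order overlap is resolved at the phantom level
#' ([snapshot()]'s additive decomposition), so this treats the primitive in
#' isolation (annulus = outer minus inner chord).
#'
#' @param fp One element of a [snapshot()] (or a list with `center`,
#'   `semi_axes`, `tilt`, `mu`, `shape`, optional `inner_semi_axes`).
#' @param ray A list with `point` and unit `dir`, as from [ray_for()].
#' @return Line integral in mm^-1 * mm.
#' @export
primitive_line_integral <- function(fp, ray) {
  ch <- chord_ellipse(fp$center, fp$semi_axes, fp$tilt %||% 0,
                      ray$point[1], ray$point[2], ray$dir[1], ray$dir[2])
  if (identical(fp$shape, "annulus"))
    ch <- ch - chord_ellipse(fp$center, fp$inner_semi_axes, fp$tilt %||% 0,
                             ray$point[1], ray$point[2], ray$dir[1], ray$dir[2])
  out <- fp$mu * ch
  if (identical(fp$shape, "notched_rod"))
    out <- out + (fp$notch_mu - fp$mu) *
      chord_ellipse(fp$notch_center, fp$notch_semi_axes, 0,
                    ray$point[1], ray$point[2], ray$dir[1], ray$dir[2])
  out
}

#' Time-resolved fan-beam forward projection
#'
#' Projects the dynamic phantom view by view: row `v` of the sinogram holds
#' the analytic line integrals of `snapshot(phantom, view_times[v])`, so the
#' object moves between views exactly as it would during a real scan.
#' Deterministic and noiseless; see [add_noise()] for photon noise.
#'
#' @param phantom A [dynamic_phantom()].
#' @param geometry A [system_geometry()].
#' @param timeline A [scan_timeline()].
#' @return An object of class `fan_sinogram` with `values`
#'   (`n_views x n_channels`, mm^-1 * mm), `geometry`, `timeline`, and the
#'   phantom's `ecg`.
#' @export
forward_project <- function(phantom, geometry, timeline) {
  stopifnot(inherits(phantom, "dynamic_phantom"),
            inherits(geometry, "system_geometry"),
            inherits(timeline, "scan_timeline"))
  if (phantom$fov_extent / 2 > scan_fov_radius(geometry) + 1e-9)
    stop("phantom extends beyond the scan FOV; truncated projections are not supported")
  nc <- geometry$n_channels
  dg <- geometry$fan_angle_rad / (nc - 1)
  gamma <- ((0:(nc - 1)) - (nc - 1) / 2) * dg
  R <- geometry$source_to_iso
  nv <- timeline$n_views
  values <- matrix(0, nv, nc)
  for (v in seq_len(nv)) {
    beta <- timeline$view_angles[v]
    fr <- snapshot(phantom, timeline$view_times[v])
    theta <- beta + gamma
    values[v, ] <- frozen_line_integral(fr,
      qx = rep(-R * sin(beta), nc), qy = rep(R * cos(beta), nc),
      ux = sin(theta), uy = -cos(theta))
  }
  structure(list(values = values, geometry = geometry, timeline = timeline,
                 ecg = phantom$ecg),
            class = "fan_sinogram")
}

#' @export
print.fan_sinogram <- function(x, ...) {
  cat(sprintf("<fan_sinogram> %d views x %d channels, t = [%.4f, %.4f] s\n",
              nrow(x$values), ncol(x$values),
              min(x$timeline$view_times), max(x$timeline$view_times)))
  invisible(x)
}

#' Add Poisson photon noise to a sinogram
#'
#' Models transmission counts `Poisson(photons * exp(-p))` per ray and
#' returns the re-log-transformed line integrals. Counts are clipped at a
#' floor of 1 photon before the log (documented floor; relevant only for
#' extremely attenuating rays). Reproducible for a fixed seed; the caller's
#' RNG state is preserved.
#'
#' @param sino A `fan_sinogram`.
#' @param photons_per_ray Incident photons per ray (> 0).
#' @param seed Integer seed.
#' @return A `fan_sinogram` with noisy values.
#' @export
add_noise <- function(sino, photons_per_ray, seed = 1L) {
  stopifnot(inherits(sino, "fan_sinogram"))
  if (!is.numeric(photons_per_ray) || photons_per_ray <= 0)
    stop("photons_per_ray must be positive")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  counts <- stats::rpois(length(sino$values),
                         photons_per_ray * exp(-sino$values))
  counts <- pmax(counts, 1)
  sino$values <- matrix(-log(counts / photons_per_ray),
                        nrow(sino$values), ncol(sino$values))
  sino
}
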
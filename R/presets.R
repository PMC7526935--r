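#' Dynamic phantom presets
#'
#' Ready-made [dynamic_phantom()]s emulating the three evaluation objects
#' used throughout the package:
#'
#' * `"xcat_like"` — beating-heart analog: a contracting myocardial-wall
#'   annulus, two blood-pool chambers with distinct contrast (left- vs
#'   right-heart analog), and three small high-contrast disks riding on the
#'   wall standing in for the RCA, LAD and LCX coronary arteries. Structure
#'   parameters interpolate between a diastolic (relaxed) and a systolic
#'   (contracted) configuration under a rest-and-jerk law, so quiescent
#'   ("good") and rapidly moving ("bad") cardiac phases both exist, as in
#'   real R-R phase selection.
#' * `"mocomo_like"` — coronary-motion analog: six artery rods of diameter
#'   3/4/5 mm (one of each size with a low-density stenosis inclusion) in a
#'   water cylinder, undergoing rigid orbital rotation plus a small
#'   translation of the assembly.
#' * `"alpha_like"` — pulsating balloon (heart-chamber/myocardial-wall
#'   analog, contrast configurable in the 250-300 HU range) with two artery
#'   rods attached to its surface, moving with it.
#' * `"static"` — the `xcat_like` layout with all motion amplitudes zero.
#'
#' @param name Preset name.
#' @param heart_rate Beats per minute (default 60).
#' @param t0_rpeak First R-peak time, seconds.
#' @param motion_scale Scales all motion amplitudes (0 = frozen at the
#'   relaxed configuration, 1 = default amplitudes).
#' @param artery_d Artery-disk diameter for `xcat_like`, mm (default 3, the
#'   smallest and hardest size).
#' @param balloon_hu Balloon contrast for `alpha_like`, HU (default 275).
#' @param rest_phase,peak_phase,duty,duty_peak Rest-and-jerk law parameters
#'   for `xcat_like`. The defaults emulate cardiac kinematics: rapid
#'   contraction spanning roughly R-R 5-38%, a short end-systolic pause
#'   around 38-44% (`peak_phase` 0.41, `duty_peak` 0.06), fast
#'   early-diastolic relaxation ending near R-R 53%, and a long diastasis
#'   quiescent window from about 53% to 105% of the cycle (`rest_phase`
#'   0.79, `duty` 0.52), so R-R 30% is a fast-moving ("bad") phase and R-R
#'   70% a quiescent ("good") one.
#' @param sway Amplitude (mm, x and y) of a small whole-heart harmonic
#'   drift present throughout the cycle — even diastasis is not perfectly
#'   still in vivo. Scaled by `motion_scale`.
#' @param mu_water Water attenuation, mm^-1, for HU conversion.
#' @return A [dynamic_phantom()].
#' @export
preset_phantom <- function(name = c("xcat_like", "mocomo_like", "alpha_like",
                                    "static"),
                           heart_rate = 60, t0_rpeak = 0, motion_scale = 1,
                           artery_d = 3, balloon_hu = 275,
                           rest_phase = 0.79, peak_phase = 0.41, duty = 0.52,
                           duty_peak = 0.06, sway = c(1.0, 0.7),
                           mu_water = 0.02) {
  if (is.character(name) && length(name) == 1 &&
      !(name %in% c("xcat_like", "mocomo_like", "alpha_like", "static")))
    stop(sprintf("unknown phantom preset '%s'", name))
  name <- match.arg(name)
  ecg <- ecg_model(heart_rate, t0_rpeak)
  hu <- function(h) hu_to_mu(h, mu_water)
  switch(name,
    "static" = xcat_like_phantom(ecg, 0, artery_d, rest_phase, peak_phase,
                                 duty, duty_peak, c(0, 0), hu),
    "xcat_like" = xcat_like_phantom(ecg, motion_scale, artery_d, rest_phase,
                                    peak_phase, duty, duty_peak, sway, hu),
    "mocomo_like" = mocomo_like_phantom(ecg, motion_scale, hu),
    "alpha_like" = alpha_like_phantom(ecg, motion_scale, balloon_hu, hu))
}

# interpolate between a diastolic and a systolic parameter vector with the
# rest-and-jerk activation a(phase) in [0,1]
lerp_cfg <- function(dia, sys, act) {
  force(dia); force(sys); force(act)
  function(phase) {
    a <- act(phase)
    dia + a * (sys - dia)
  }
}

xcat_like_phantom <- function(ecg, motion_scale, artery_d, rest_phase,
                              peak_phase, duty, duty_peak, sway, hu) {
  law <- motion_law("rest-and-jerk", amplitude = 1,
                    phase_of_rest = rest_phase, duty = duty,
                    phase_of_peak = peak_phase, duty_peak = duty_peak)
  act <- function(phase) motion_scale * motion_value(law, phase)
  sway <- sway * motion_scale
  wob <- function(phase) c(sway[1] * sin(2 * pi * phase),
                           sway[2] * cos(2 * pi * phase))
  wob_amp <- sqrt(sum(sway^2))
  # configuration interpolation plus the whole-heart sway
  lerp_c <- function(dia, sys) {
    force(dia); force(sys)
    function(phase) dia + act(phase) * (sys - dia) + wob(phase)
  }

  wall_out_d <- c(45, 40); wall_out_s <- c(40, 35.5)
  wall_in_d  <- c(30, 26); wall_in_s  <- c(24, 20.5)

  arty_r <- artery_d / 2
  arty_angles <- c(100, 215, 340) * pi / 180
  mid_d <- (wall_out_d + wall_in_d) / 2
  mid_s <- (wall_out_s + wall_in_s) / 2

  prim <- list(
    tv_primitive("body", "ellipse", hu(0), c(0, 0), c(200, 160)),
    tv_primitive("myocardium", "annulus", hu(100), lerp_c(c(0, 0), c(0, 0)),
                 lerp_cfg(wall_out_d, wall_out_s, act),
                 inner_semi_axes = lerp_cfg(wall_in_d, wall_in_s, act),
                 amplitude = wob_amp + 1e-9),
    tv_primitive("LV", "ellipse", hu(350),
                 lerp_c(c(-10, 0), c(-8, 0)),
                 lerp_cfg(c(12, 10), c(8, 6.5), act),
                 amplitude = 2 * motion_scale + wob_amp + 1e-9),
    tv_primitive("RV", "ellipse", hu(180),
                 lerp_c(c(11, 0), c(9, 0)),
                 lerp_cfg(c(9, 8), c(6, 5), act),
                 amplitude = 2 * motion_scale + wob_amp + 1e-9))
  labs <- c("RCA", "LAD", "LCX")
  for (i in seq_along(arty_angles)) {
    phi <- arty_angles[i]
    cd <- mid_d * c(cos(phi), sin(phi))
    cs <- mid_s * c(cos(phi), sin(phi))
    prim[[length(prim) + 1]] <-
      tv_primitive(labs[i], "ellipse", hu(450),
                   lerp_c(cd, cs), c(arty_r, arty_r),
                   amplitude = motion_scale * sqrt(sum((cs - cd)^2)) +
                     wob_amp + 1e-9)
  }
  dynamic_phantom(prim, ecg, fov_extent = 404)
}

mocomo_like_phantom <- function(ecg, motion_scale, hu) {
  orbit_amp <- 0.16 * motion_scale      # radians; 8 mm at 50 mm radius
  trans_amp <- 2 * motion_scale         # mm
  law_rest <- 0.75
  angle_at <- function(phase) orbit_amp * sin(2 * pi * (phase - law_rest))
  shift_at <- function(phase) trans_amp * sin(2 * pi * (phase - law_rest))

  rod_d <- c(3, 4, 5, 3, 4, 5)
  rod_hu <- c(350, 400, 450, 350, 400, 450)
  rod_phi <- (0:5) * pi / 3
  stenosed <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  ring_r <- 50

  # factory so each rod's closure captures its own anchor point
  orbit_ctr <- function(anchor) {
    force(anchor)
    function(phase) {
      a <- angle_at(phase)
      orbit_offset(anchor, c(0, 0), a) + c(shift_at(phase), 0)
    }
  }
  prim <- list(tv_primitive("water", "ellipse", hu(0), c(0, 0), c(80, 80)))
  for (i in 1:6) {
    r <- rod_d[i] / 2
    p0 <- ring_r * c(cos(rod_phi[i]), sin(rod_phi[i]))
    ctr <- orbit_ctr(p0)
    lab <- sprintf("rod%d_%gmm%s", i, rod_d[i],
                   if (stenosed[i]) "_sten" else "")
    if (stenosed[i]) {
      # low-density interior inclusion: the stenosis analog
      nctr <- orbit_ctr(p0 + r * 0.4 * c(cos(rod_phi[i]), sin(rod_phi[i])))
      prim[[length(prim) + 1]] <-
        tv_primitive(lab, "notched_rod", hu(rod_hu[i]), ctr, c(r, r),
                     notch_center = nctr,
                     notch_semi_axes = c(r * 0.45, r * 0.45),
                     notch_mu = hu(50),
                     amplitude = ring_r * orbit_amp + trans_amp + 0.1)
    } else {
      prim[[length(prim) + 1]] <-
        tv_primitive(lab, "ellipse", hu(rod_hu[i]), ctr, c(r, r),
                     amplitude = ring_r * orbit_amp + trans_amp + 1e-9)
    }
  }
  dynamic_phantom(prim, ecg, fov_extent = 164)
}

alpha_like_phantom <- function(ecg, motion_scale, balloon_hu, hu) {
  amp <- 4 * motion_scale
  r_at <- function(phase) 30 + amp * sin(2 * pi * (phase - 0.75))
  rod_r <- 2
  rod_phi <- c(45, 200) * pi / 180
  prim <- list(
    tv_primitive("water", "ellipse", hu(0), c(0, 0), c(70, 70)),
    tv_primitive("balloon", "ellipse", hu(balloon_hu), c(0, 0),
                 function(phase) rep(r_at(phase), 2), amplitude = 0))
  surf_ctr <- function(phi) {
    force(phi)
    function(phase) (r_at(phase) + rod_r + 0.2) * c(cos(phi), sin(phi))
  }
  for (i in seq_along(rod_phi)) {
    ctr <- surf_ctr(rod_phi[i])
    prim[[length(prim) + 1]] <-
      tv_primitive(sprintf("rod%d", i), "ellipse", hu(450), ctr,
                   c(rod_r, rod_r), amplitude = amp + 1e-9)
  }
  dynamic_phantom(prim, ecg, fov_extent = 144)
}
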
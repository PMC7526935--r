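#' ECG model
#'
#' A periodic cardiac-cycle clock. The cycle period is `60 / heart_rate`
#' seconds and phase 0 corresponds to an R peak, so "R-R 30%" means cardiac
#' phase 0.3.
#'
#' @param heart_rate Heart rate in beats per minute (> 0).
#' @param t0_rpeak Time of the first R peak, seconds.
#' @return An object of class `ecg_model`.
#' @export
ecg_model <- function(heart_rate, t0_rpeak = 0) {
  if (!is.numeric(heart_rate) || length(heart_rate) != 1 || heart_rate <= 0)
    stop("heart_rate must be a positive scalar (beats per minute)")
  structure(list(heart_rate = heart_rate, t0_rpeak = t0_rpeak,
                 period = 60 / heart_rate),
            class = "ecg_model")
}

#' Cardiac phase at a time point
#'
#' Maps absolute time to the R-R fraction in `[0, 1)`:
#' `((t - t0_rpeak) mod period) / period` with `period = 60 / heart_rate`.
#'
#' @param ecg An [ecg_model()].
#' @param t Time(s), seconds (vectorised).
#' @return Phase fraction(s) in `[0, 1)`.
#' @export
cardiac_phase <- function(ecg, t) {
  stopifnot(inherits(ecg, "ecg_model"))
  ph <- ((t - ecg$t0_rpeak) / ecg$period) %% 1
  # numerical wrap: exactly one period later must give exactly 0
  ph[ph >= 1] <- 0
  ph
}

#' Time of a cardiac phase within a given cycle
#'
#' Inverse of [cardiac_phase()] restricted to one cycle:
#' `t0_rpeak + (cycle_index + phase) * period`.
#'
#' @param ecg An [ecg_model()].
#' @param phase R-R fraction in `[0, 1)`.
#' @param cycle_index 0-based index of the cardiac cycle.
#' @return Time in seconds.
#' @export
phase_time <- function(ecg, phase, cycle_index = 0) {
  stopifnot(inherits(ecg, "ecg_model"), phase >= 0, phase < 1)
  ecg$t0_rpeak + (cycle_index + phase) * ecg$period
}

#' Periodic motion law
#'
#' Scalar activation/displacement profiles driving the dynamic phantom, all
#' periodic and continuous in cardiac phase with `max |displacement| <=
#' amplitude`:
#'
#' * `harmonic` — `amplitude * sin(2*pi*(phase - phase_of_rest))`.
#' * `rest-and-jerk` — smoothstep switching between two configurations with
#'   flat rest plateaus (half-width `duty/2`) around `phase_of_rest`
#'   (activation 0) and a second rest phase (activation 1); emulates the
#'   diastasis/end-systole quiescent windows of the cardiac cycle.
#' * `rigid-orbit` — position advances around a circle of radius `amplitude`
#'   (used via [orbit_offset()]).
#' * `triangle` — triangle wave, exactly linear in phase on
#'   `(0.05, 0.45)` and `(0.55, 0.95)`; useful when a locally linear-in-time
#'   trajectory is wanted inside a sub-cycle window.
#'
#' @param kind One of `"harmonic"`, `"rest-and-jerk"`, `"rigid-orbit"`,
#'   `"triangle"`.
#' @param amplitude Peak displacement (mm) or activation scale.
#' @param phase_of_rest Phase of the (first) rest window, fraction in `[0,1)`.
#' @param duty Fraction of the cycle spent near rest (plateau width of the
#'   `phase_of_rest` window for `rest-and-jerk`).
#' @param phase_of_peak Phase of the second (activation 1) rest window for
#'   `rest-and-jerk`.
#' @param duty_peak Plateau width of the `phase_of_peak` window (defaults
#'   to `duty`); separate widths let the quiescent diastasis window be much
#'   longer than the end-systolic pause, as in real cardiac kinematics.
#' @return An object of class `motion_law`; call it via [motion_value()].
#' @export
motion_law <- function(kind = c("harmonic", "rest-and-jerk", "rigid-orbit",
                                "triangle"),
                       amplitude = 1, phase_of_rest = 0.75, duty = 0.15,
                       phase_of_peak = 0.4, duty_peak = duty) {
  kind <- match.arg(kind)
  stopifnot(amplitude >= 0, phase_of_rest >= 0, phase_of_rest < 1,
            duty >= 0, duty < 0.9, duty_peak >= 0, duty_peak < 0.9)
  structure(list(kind = kind, amplitude = amplitude,
                 phase_of_rest = phase_of_rest, duty = duty,
                 phase_of_peak = phase_of_peak, duty_peak = duty_peak),
            class = "motion_law")
}

smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# Activation in [0,1] for the rest-and-jerk law: 0 on a plateau of half-width
# duty/2 around phase_of_rest, 1 on a plateau of half-width duty_peak/2
# around phase_of_peak, C1 smoothstep transitions in between. Periodic.
rj_activation <- function(phase, phase_of_rest, phase_of_peak, duty,
                          duty_peak = duty) {
  hr <- duty / 2; hp <- duty_peak / 2
  # distance forward from the rest plateau centre to the peak plateau centre
  d1 <- (phase_of_peak - phase_of_rest) %% 1
  up_len <- d1 - hr - hp
  dn_len <- (1 - d1) - hr - hp
  if (up_len <= 0 || dn_len <= 0)
    stop("rest and peak plateaus overlap; reduce duty")
  # phase measured forward from the rest-plateau centre
  u <- (phase - phase_of_rest) %% 1
  a <- numeric(length(u))
  rising <- u > hr & u < hr + up_len
  a[rising] <- smoothstep((u[rising] - hr) / up_len)
  peak <- u >= hr + up_len & u <= d1 + hp
  a[peak] <- 1
  falling <- u > d1 + hp & u < 1 - hr
  a[falling] <- smoothstep(1 - (u[falling] - d1 - hp) / dn_len)
  a
}

# triangle wave in [-1, 1]: linear with slope -4 on (0, 0.5), +4 on
# (0.5, 1); turning points at phase 0 and 0.5, zero mean, period 1
tri_wave <- function(phase) {
  u <- phase %% 1
  ifelse(u <= 0.5, 1 - 4 * u, 4 * u - 3)
}

#' Evaluate a motion law
#'
#' @param law A [motion_law()].
#' @param phase Cardiac phase(s) in `[0, 1)` (vectorised).
#' @return Displacement (mm) for `harmonic`/`triangle`, activation in `[0,1]`
#'   scaled by `amplitude` for `rest-and-jerk`, orbit angle advance (radians)
#'   for `rigid-orbit`.
#' @export
motion_value <- function(law, phase) {
  stopifnot(inherits(law, "motion_law"))
  switch(law$kind,
    "harmonic" = law$amplitude * sin(2 * pi * (phase - law$phase_of_rest)),
    "rest-and-jerk" = law$amplitude *
      rj_activation(phase, law$phase_of_rest, law$phase_of_peak, law$duty,
                    law$duty_peak),
    "rigid-orbit" = law$amplitude * sin(2 * pi * (phase - law$phase_of_rest)),
    "triangle" = law$amplitude * tri_wave(phase))
}

# Offset on a circular orbit for the rigid-orbit law: the assembly rotates by
# angle_amp*sin(2*pi*(phase - phase_of_rest)) about `center`; returns the
# rotated position of point p0.
orbit_offset <- function(p0, center, angle) {
  dx <- p0[1] - center[1]; dy <- p0[2] - center[2]
  c(center[1] + cos(angle) * dx - sin(angle) * dy,
    center[2] + sin(angle) * dx + cos(angle) * dy)
}
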
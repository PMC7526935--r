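#' Default run configuration
#'
#' Nested list of every tunable parameter with its default: the 52 degree
#' fan/PAR angle, 0.25 s rotation, `pi + 2*fan` gating window, `[0.1, 0.3]`
#' pi rad/sample band-pass, 3.6 mm finest control spacing with three
#' multi-resolution levels, and the 14.3 mm displacement cap.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    phantom = list(preset = "xcat_like", heart_rate = 60, t0_rpeak = 0,
                   motion_scale = 1, artery_d = 3, balloon_hu = 275,
                   rest_phase = 0.79, peak_phase = 0.41, duty = 0.52,
                   duty_peak = 0.06, sway = c(1.0, 0.7)),
    geometry = list(source_to_iso = 570, source_to_detector = 1040,
                    n_channels = 736, fan_angle = 52,
                    views_per_rotation = 720, rotation_time = 0.25),
    scan = list(n_rotations = 2, start_time = 0, noise_photons = NULL,
                seed = 1),
    recon = list(grid_n = 256, fov = 250, target_phases = c(0.3, 0.7),
                 cycle_index = 0, apodization = "none", mu_water = 0.02),
    motion = list(f_lo = 0.1, f_hi = 0.3, levels = 3, grid_spacing = 3.6,
                  lambda = 1e-3, maxit = 150, displacement_cap = 14.3),
    metrics = list(roi_half_extent = 10, profile_samples = 50)
  )
}

merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

#' Load and validate a YAML run configuration
#'
#' Unknown keys are rejected; missing keys take the [default_config()]
#' values.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return Validated configuration list.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    over <- yaml::read_yaml(path)
    problems <- character()
    for (sec in names(over)) {
      if (!sec %in% names(cfg)) {
        problems <- c(problems, sprintf("unknown section '%s'", sec))
        next
      }
      bad <- setdiff(names(over[[sec]]), names(cfg[[sec]]))
      if (length(bad))
        problems <- c(problems,
                      sprintf("unknown key(s) in '%s': %s", sec,
                              paste(bad, collapse = ", ")))
    }
    if (length(problems))
      stop("invalid configuration: ", paste(problems, collapse = "; "))
    cfg <- merge_config(cfg, over)
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  ck <- function(test, msg) if (!isTRUE(test)) stop("invalid configuration: ", msg)
  ck(cfg$phantom$heart_rate > 0, "heart_rate must be positive")
  ck(cfg$geometry$fan_angle > 0 && cfg$geometry$fan_angle < 90,
     "fan_angle must be in (0, 90) degrees")
  ck(cfg$geometry$rotation_time > 0, "rotation_time must be positive")
  ck(cfg$motion$f_lo < cfg$motion$f_hi, "band-pass needs f_lo < f_hi")
  ck(cfg$motion$displacement_cap > 0, "displacement_cap must be positive")
  ck(cfg$recon$grid_n >= 16, "recon grid too small")
  ck(all(cfg$recon$target_phases >= 0 & cfg$recon$target_phases < 1),
     "target phases must be in [0, 1)")
  invisible(cfg)
}

config_phantom <- function(cfg) {
  p <- cfg$phantom
  preset_phantom(p$preset, heart_rate = p$heart_rate, t0_rpeak = p$t0_rpeak,
                 motion_scale = p$motion_scale, artery_d = p$artery_d,
                 balloon_hu = p$balloon_hu, rest_phase = p$rest_phase,
                 peak_phase = p$peak_phase, duty = p$duty,
                 duty_peak = p$duty_peak, sway = p$sway,
                 mu_water = cfg$recon$mu_water)
}

config_geometry <- function(cfg) {
  g <- cfg$geometry
  system_geometry(g$source_to_iso, g$source_to_detector, g$n_channels,
                  g$fan_angle, g$views_per_rotation, g$rotation_time)
}

config_grid <- function(cfg) {
  recon_grid(cfg$recon$grid_n, cfg$recon$fov / cfg$recon$grid_n)
}

config_regcfg <- function(cfg) {
  m <- cfg$motion
  registration_config(levels = m$levels, spacing = m$grid_spacing,
                      lambda = m$lambda, maxit = m$maxit,
                      displacement_cap = m$displacement_cap)
}

#' Simulate a scan from a configuration
#'
#' Builds the configured phantom, geometry and timeline, forward projects,
#' and optionally adds Poisson noise (`scan$noise_photons`; off by default
#' so that algorithm performance is measured without noise).
#'
#' @param cfg Configuration list from [load_run_config()] /
#'   [default_config()].
#' @return A `fan_sinogram`.
#' @export
simulate_scan <- function(cfg = default_config()) {
  validate_config(cfg)
  phantom <- config_phantom(cfg)
  geometry <- config_geometry(cfg)
  timeline <- scan_timeline(geometry, cfg$scan$n_rotations,
                            start_time = cfg$scan$start_time)
  sino <- forward_project(phantom, geometry, timeline)
  if (!is.null(cfg$scan$noise_photons))
    sino <- add_noise(sino, cfg$scan$noise_photons, cfg$scan$seed)
  sino
}
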
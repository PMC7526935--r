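#' Generate the regression fixture suite
#'
#' Simulates the 3-preset x 3-heart-rate x 2-phase suite (18 cases): for
#' each case a fan-beam scan (HDF5) and the supersampled ground-truth image
#' at each target phase (NIfTI), plus a `manifest.csv` with parameters and
#' MD5 checksums. Deterministic: re-running with the same seed reproduces
#' identical files.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Seed for any noisy scans (default runs are noiseless, so the
#'   seed only enters through [add_noise()] when `noise_photons` is set).
#' @param cfg Base configuration controlling problem size.
#' @param presets,heart_rates,phases Case axes.
#' @return The manifest `data.frame`, invisibly.
#' @export
make_fixtures <- function(outdir, seed = 1,
                          cfg = default_config(),
                          presets = c("xcat_like", "mocomo_like", "alpha_like"),
                          heart_rates = c(60, 80, 100),
                          phases = c(0.3, 0.7)) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  grid <- config_grid(cfg)
  rows <- list()
  for (preset in presets) for (hr in heart_rates) {
    ccfg <- cfg
    ccfg$phantom$preset <- preset
    ccfg$phantom$heart_rate <- hr
    ccfg$scan$seed <- seed
    ccfg$scan$n_rotations <- max(ccfg$scan$n_rotations,
                                 ceiling((60 / hr + 0.3) /
                                         ccfg$geometry$rotation_time))
    phantom <- config_phantom(ccfg)
    sino <- simulate_scan(ccfg)
    scan_file <- file.path(outdir, sprintf("%s_hr%d.h5", preset, hr))
    write_scan(sino, scan_file)
    for (ph in phases) {
      w <- select_gating_window(sino$timeline, sino$ecg, ph, sino$geometry,
                                ccfg$recon$cycle_index)
      gt <- rasterize(snapshot(phantom, w$target_time), grid,
                      supersample = 4, mu_water = ccfg$recon$mu_water)
      gt_file <- file.path(outdir,
                           sprintf("%s_hr%d_ph%02.0f_truth.nii.gz",
                                   preset, hr, 100 * ph))
      write_image_nifti(gt, gt_file)
      rows[[length(rows) + 1]] <- data.frame(
        case = sprintf("%s_hr%d_ph%02.0f", preset, hr, 100 * ph),
        preset = preset, heart_rate = hr, phase = ph,
        scan = basename(scan_file), truth = basename(gt_file),
        window_first = w$first, window_last = w$last,
        target_time = w$target_time,
        scan_md5 = unname(tools::md5sum(scan_file)),
        truth_md5 = unname(tools::md5sum(gt_file)))
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
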
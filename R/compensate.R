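#' Linear-in-time scaling of a motion field
#'
#' The linear motion model: the displacement of a structure at view time `t`
#' relative to the target time is `alpha(t) * d(x)` with `alpha(t) =
#' (t - target_time) / (t_end - t_start)`. By default the target is the
#' midpoint of the two PAR centre times, so `alpha` runs from -1/2 at the
#' first PAR to +1/2 at the last and is 0 at the target.
#'
#' @param mvf A [motion_vector_field()] with finite `t_start`, `t_end`.
#' @param t Time, seconds; must lie within `[t_start, t_end]` (a small
#'   tolerance of one per cent of the interval is allowed for view-time
#'   rounding).
#' @param target_time Target time (default midpoint).
#' @return List with `alpha` and a function `displace(points)` returning the
#'   scaled displacements.
#' @export
temporal_scale <- function(mvf, t, target_time = (mvf$t_start + mvf$t_end) / 2) {
  stopifnot(inherits(mvf, "motion_vector_field"),
            is.finite(mvf$t_start), is.finite(mvf$t_end))
  dt <- mvf$t_end - mvf$t_start
  tol <- 0.01 * dt
  if (t < mvf$t_start - tol || t > mvf$t_end + tol)
    stop("time outside the gating window spanned by the motion field")
  alpha <- (t - target_time) / dt
  list(alpha = alpha,
       displace = function(points) alpha * ffd_displace(mvf, points))
}

#' Motion-compensated weighted backprojection
#'
#' Backprojects a ramp-filtered parallel sinogram while moving each
#' target-frame pixel to its position at the acquisition time of every row:
#' pixel `x` accumulates `w(theta, s') * p_hat(theta, s')` at `s' = (x +
#' alpha(t_row) * d(x)) . (cos theta, sin theta)`. The dense displacement
#' `d` is evaluated once on the reconstruction grid; rows only rescale it
#' by their `alpha`, so the cost is close to plain backprojection. With an
#' all-zero field the result is bit-identical to [backproject()].
#' Contributions whose displaced radial position leaves the measured range
#' are dropped and counted.
#'
#' @param psino A ramp-filtered `parallel_sinogram` (with `row_times`).
#' @param weights Redundancy weight matrix.
#' @param mvf A [motion_vector_field()] covering the grid.
#' @param grid A [recon_grid()].
#' @param target_time Target time (default: midpoint of the field's times).
#' @param mu_water Water attenuation for HU metadata.
#' @return A [recon_image()] with attribute `dropped` (count of discarded
#'   contributions).
#' @export
mc_backproject <- function(psino, weights, mvf, grid,
                           target_time = (mvf$t_start + mvf$t_end) / 2,
                           mu_water = 0.02) {
  stopifnot(inherits(psino, "parallel_sinogram"),
            inherits(mvf, "motion_vector_field"),
            inherits(grid, "recon_grid"),
            all(dim(weights) == dim(psino$values)))
  dd <- ffd_dense(mvf, grid$centers, grid$centers)
  dt <- mvf$t_end - mvf$t_start
  alphas <- (psino$row_times - target_time) / dt
  bp <- backproject_core(psino$values, weights, psino$par_angles,
                         psino$radial, grid,
                         Dx = dd$Dx, Dy = dd$Dy, alphas = alphas)
  img <- recon_image(bp$values, grid, mu_water = mu_water,
                     time = target_time)
  attr(img, "dropped") <- bp$dropped
  img
}

#' Motion-corrected reconstruction from a sub-rotation gating window
#'
#' Runs the full correction pipeline at a target cardiac phase: gating
#' window selection (width `pi + 2 * fan`), fan-to-parallel rebinning, ramp
#' filtering, conjugate partial-angle reconstruction from the first and
#' last `fan` degrees of views, band-pass edge extraction, multi-resolution
#' FFD registration between the two PAR images, and motion-compensated
#' weighted backprojection with the linear motion model targeting the
#' midpoint of the two PAR times. The uncorrected short-scan FBP image from
#' the same window is returned alongside for comparison.
#'
#' @param fan_sino A `fan_sinogram` carrying its `ecg`.
#' @param target_phase R-R fraction to reconstruct.
#' @param grid A [recon_grid()].
#' @param cycle_index Cardiac cycle (0-based).
#' @param f_lo,f_hi Band-pass edges, pi rad/sample.
#' @param reg A [registration_config()].
#' @param apodization Ramp-filter apodization.
#' @param compute_fbp Also compute the plain FBP image (default TRUE).
#' @param keep_diagnostics Keep PAR and band-passed PAR images in the result.
#' @param mu_water Water attenuation reference, mm^-1.
#' @return An object of class `sculli_recon` with elements `image`
#'   (motion-corrected [recon_image()]), `fbp`, `mvf`, `window`, timings and
#'   optional per-stage diagnostics. Methods: `print`, `summary`, `plot`,
#'   `coef` (control displacements).
#' @export
sculli_reconstruct <- function(fan_sino, target_phase, grid, cycle_index = 0,
                               f_lo = 0.1, f_hi = 0.3,
                               reg = registration_config(),
                               apodization = "none", compute_fbp = TRUE,
                               keep_diagnostics = FALSE, mu_water = 0.02) {
  stopifnot(inherits(fan_sino, "fan_sinogram"), inherits(grid, "recon_grid"))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    list(value = out, elapsed = proc.time()[["elapsed"]] - t0)
  }
  timings <- c()
  s <- stage("gating", select_gating_window(fan_sino$timeline, fan_sino$ecg,
                                            target_phase, fan_sino$geometry,
                                            cycle_index))
  window <- s$value; timings["gating"] <- s$elapsed
  s <- stage("rebin", rebin(fan_sino, window))
  psino <- s$value; timings["rebin"] <- s$elapsed
  s <- stage("filter", ramp_filter(psino, apodization))
  psino <- s$value; timings["filter"] <- s$elapsed
  weights <- redundancy_weights(psino)
  s <- stage("par", list(first = reconstruct_par(psino, grid, "first",
                                                 mu_water = mu_water),
                         last = reconstruct_par(psino, grid, "last",
                                                mu_water = mu_water)))
  pars <- s$value; timings["par"] <- s$elapsed
  s <- stage("estimate_motion",
             estimate_motion(pars$first, pars$last, f_lo, f_hi, reg))
  mvf <- s$value; timings["estimate_motion"] <- s$elapsed
  s <- stage("mc_backproject",
             mc_backproject(psino, weights, mvf, grid, mu_water = mu_water))
  image <- s$value; timings["mc_backproject"] <- s$elapsed
  image$phase <- target_phase
  fbp <- NULL
  if (compute_fbp) {
    s <- stage("fbp", backproject(psino, weights, grid, mu_water = mu_water))
    fbp <- s$value; timings["fbp"] <- s$elapsed
  }
  out <- list(image = image, fbp = fbp, mvf = mvf, window = window,
              target_phase = target_phase, grid = grid,
              timings = timings, dropped = attr(image, "dropped"))
  if (keep_diagnostics) {
    out$par_first <- pars$first
    out$par_last <- pars$last
    out$bp_first <- bandpass(pars$first$image, f_lo, f_hi)
    out$bp_last <- bandpass(pars$last$image, f_lo, f_hi)
  }
  structure(out, class = "sculli_recon")
}

#' @export
print.sculli_recon <- function(x, ...) {
  cat(sprintf("<sculli_recon> phase %.2f (target time %.4f s)\n",
              x$target_phase, x$window$target_time))
  cat(sprintf("  window: views %d..%d, %.1f deg of tube angle\n",
              x$window$first, x$window$last, x$window$width * 180 / pi))
  d <- dim(x$mvf$controls)
  dd <- ffd_dense(x$mvf, x$grid$centers, x$grid$centers)
  cat(sprintf("  motion field: %d x %d controls @ %.1f mm, max |d| %.2f mm\n",
              d[1], d[2], x$mvf$spacing, sqrt(max(dd$Dx^2 + dd$Dy^2))))
  cat(sprintf("  dropped contributions: %d\n", x$dropped))
  invisible(x)
}

#' @export
summary.sculli_recon <- function(object, ...) {
  x <- object
  print(x)
  cat("  stage timings (s):\n")
  for (nm in names(x$timings))
    cat(sprintf("    %-16s %6.2f\n", nm, x$timings[[nm]]))
  lv <- x$mvf$diagnostics$levels
  if (!is.null(lv)) {
    cat("  registration objective per level:\n")
    for (l in lv)
      cat(sprintf("    %.1f mm grid: %.4g -> %.4g (%d evals)\n",
                  l$spacing, l$objective_initial, l$objective_final,
                  l$counts[["function"]]))
  }
  invisible(x)
}

#' @export
plot.sculli_recon <- function(x, what = c("corrected", "fbp", "mvf"), ...) {
  what <- match.arg(what)
  switch(what,
         corrected = plot(x$image, main = "motion-corrected", ...),
         fbp = if (is.null(x$fbp)) stop("FBP image was not computed")
               else plot(x$fbp, main = "FBP", ...),
         mvf = plot(x$mvf, ...))
  invisible(x)
}

#' @export
coef.sculli_recon <- function(object, ...) coef(object$mvf)
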
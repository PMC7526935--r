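#' Select the gating window for a target cardiac phase
#'
#' Picks the contiguous run of views whose tube angles span `pi + 2 *
#' fan_angle` radians (the short-scan-plus-fan window needed for conjugate
#' partial-angle reconstruction), centred on the view whose acquisition time
#' is closest to the target phase within the chosen cardiac cycle.
#'
#' @param timeline A [scan_timeline()].
#' @param ecg An [ecg_model()].
#' @param target_phase R-R fraction in `[0, 1)`.
#' @param geometry A [system_geometry()].
#' @param cycle_index Which cardiac cycle to reconstruct (0-based).
#' @param width Window width in radians of tube angle; default
#'   `pi + 2 * fan_angle`.
#' @return An object of class `gating_window` with the view index range,
#'   `target_time`, `target_phase`, and the realised angular width.
#' @export
select_gating_window <- function(timeline, ecg, target_phase, geometry,
                                 cycle_index = 0,
                                 width = pi + 2 * geometry$fan_angle_rad) {
  stopifnot(inherits(timeline, "scan_timeline"), inherits(ecg, "ecg_model"),
            target_phase >= 0, target_phase < 1)
  if (width >= 2 * pi) stop("gating window must be less than a full rotation")
  target_time <- phase_time(ecg, target_phase, cycle_index)
  center <- which.min(abs(timeline$view_times - target_time))
  half_n <- round(width / timeline$d_angle / 2)
  lo <- center - half_n; hi <- center + half_n
  if (lo < 1 || hi > timeline$n_views)
    stop("gating window exceeds the acquired scan; simulate more rotations or pick another cycle")
  structure(list(first = lo, last = hi, center = center,
                 target_time = target_time, target_phase = target_phase,
                 width = (hi - lo) * timeline$d_angle,
                 cycle_index = cycle_index),
            class = "gating_window")
}

#' Fan-to-parallel rebinning
#'
#' Resamples the fan rays `(beta, gamma)` inside a gating window onto a
#' parallel grid `(theta, s)` using `theta = beta + gamma`, `s =
#' source_to_iso * sin(gamma)` with bilinear interpolation. The parallel
#' angle grid keeps the same increment as the view grid and is restricted to
#' the fully covered range `[beta_min + fan/2, beta_max - fan/2]`, so every
#' retained sample is backed by measured data (no invalid corner samples).
#' The radial grid spans the full measurable `|s| <= source_to_iso *
#' sin(fan/2)`. Each row is stamped with the acquisition time of the fan
#' view providing its central ray (`beta = theta`); the `+-gamma` spread of
#' source angles feeding one row is ignored, a documented approximation of
#' at most half the fan transit time.
#'
#' @param fan_sino A `fan_sinogram`.
#' @param window A [select_gating_window()] result.
#' @param n_radial Number of radial samples (default: `n_channels`).
#' @return An object of class `parallel_sinogram` with `values`
#'   (`n_par_angles x n_radial`), `par_angles`, `radial`, `row_times`.
#' @export
rebin <- function(fan_sino, window, n_radial = NULL) {
  stopifnot(inherits(fan_sino, "fan_sinogram"),
            inherits(window, "gating_window"))
  g <- fan_sino$geometry
  tl <- fan_sino$timeline
  if (is.null(n_radial)) n_radial <- g$n_channels
  idx <- window$first:window$last
  beta <- tl$view_angles[idx]
  times <- tl$view_times[idx]
  fan <- g$fan_angle_rad
  R <- g$source_to_iso
  s_max <- R * sin(fan / 2)
  radial <- seq(-s_max, s_max, length.out = n_radial)
  if (max(abs(radial)) > s_max + 1e-9)
    stop("radial grid exceeds the measurable range")
  d_theta <- tl$d_angle
  th_lo <- beta[1] + fan / 2
  th_hi <- beta[length(beta)] - fan / 2
  m <- floor((th_hi - th_lo) / d_theta + 1e-9) + 1
  par_angles <- th_lo + (0:(m - 1)) * d_theta
  gamma <- asin(radial / R)                 # per radial column
  dg <- fan / (g$n_channels - 1)
  ci <- (gamma + fan / 2) / dg              # fractional channel index
  # fractional view index per (row, column)
  vi <- outer(par_angles, gamma, "-")       # beta = theta - gamma
  vi <- (vi - beta[1]) / tl$d_angle
  CI <- matrix(ci, m, n_radial, byrow = TRUE)
  vals <- bilinear_mat(fan_sino$values[idx, , drop = FALSE], vi, CI)
  row_times <- times[1] + (par_angles - beta[1]) / tl$d_angle * tl$d_time
  structure(list(values = matrix(vals, m, n_radial),
                 par_angles = par_angles, radial = radial,
                 row_times = row_times, geometry = g, window = window),
            class = "parallel_sinogram")
}

#' Ram-Lak ramp filtering of a parallel sinogram
#'
#' Row-wise convolution with the band-limited discrete ramp kernel
#' (`h(0) = 1/(4 ds^2)`, `h(n) = -1/(pi^2 n^2 ds^2)` for odd `n`, 0 for even
#' `n`), scaled by the radial spacing, via zero-padded FFT. With correct
#' `ds` scaling, backprojection of the filtered sinogram of a disk recovers
#' its attenuation. Optional Hann apodization trades resolution for noise.
#'
#' @param psino A `parallel_sinogram`.
#' @param apodization `"none"` (default, matching noiseless studies) or
#'   `"hann"`.
#' @return The filtered `parallel_sinogram` (field `filtered = TRUE`).
#' @export
ramp_filter <- function(psino, apodization = c("none", "hann")) {
  apodization <- match.arg(apodization)
  stopifnot(inherits(psino, "parallel_sinogram"))
  n <- length(psino$radial)
  ds <- psino$radial[2] - psino$radial[1]
  L <- 2^ceiling(log2(2 * n))
  h <- numeric(L)
  h[1] <- 1 / (4 * ds^2)
  k <- 1:(n - 1)
  odd <- k[k %% 2 == 1]
  h[1 + odd] <- -1 / (pi^2 * odd^2 * ds^2)
  h[L + 1 - odd] <- -1 / (pi^2 * odd^2 * ds^2)
  H <- Re(stats::fft(h))
  if (apodization == "hann") {
    f <- c(0:(L / 2), (L / 2 - 1):1) / (L / 2)   # |freq| / Nyquist per bin
    H <- H * 0.5 * (1 + cos(pi * f))
  }
  P <- matrix(0, L, nrow(psino$values))       # rows as columns for mvfft
  P[1:n, ] <- t(psino$values)
  Q <- Re(stats::mvfft(stats::mvfft(P) * H, inverse = TRUE)) / L
  psino$values <- t(Q[1:n, , drop = FALSE]) * ds
  psino$filtered <- TRUE
  psino
}

#' Short-scan redundancy weights (parallel domain)
#'
#' Parker-style smooth cos^2 taper over the angular overlap of a short scan,
#' applied in the rebinned parallel domain: for a span `Theta >= pi` the
#' overlap is `Theta - pi`; rays measured twice get weights summing to 1
#' across the conjugate pair `(theta, s) ~ (theta + pi, -s)`, rays measured
#' once get weight 1.
#'
#' @param psino A `parallel_sinogram`.
#' @return Weight matrix (`n_par_angles x n_radial`).
#' @export
redundancy_weights <- function(psino) {
  stopifnot(inherits(psino, "parallel_sinogram"))
  th <- psino$par_angles
  span <- th[length(th)] - th[1]
  if (span < pi - 1e-9)
    stop("angular span below pi: insufficient data for short-scan weighting")
  ov <- span - pi
  w <- rep(1, length(th))
  if (ov > 0) {
    x <- th - th[1]
    lo <- x < ov
    w[lo] <- sin(pi / 2 * x[lo] / ov)^2
    hi <- (span - x) < ov
    w[hi] <- sin(pi / 2 * (span - x[hi]) / ov)^2
  }
  matrix(w, length(th), length(psino$radial))
}

# shared backprojection core: target-frame pixel x is mapped to
# x' = x + alpha(t_row) * D(x) before the radial lookup; with a zero/absent
# field this is plain parallel-beam backprojection. Returns the image matrix
# and the count of contributions dropped because the displaced point left
# the measured radial range.
backproject_core <- function(values, weights, par_angles, radial, grid,
                             Dx = NULL, Dy = NULL, alphas = NULL) {
  n <- grid$n
  X <- matrix(grid$centers, n, n)
  Y <- t(X)
  s0 <- radial[1]
  ds <- radial[2] - radial[1]
  ns <- length(radial)
  d_theta <- par_angles[2] - par_angles[1]
  acc <- matrix(0, n, n)
  dropped <- 0L
  moving <- !is.null(Dx)
  for (j in seq_along(par_angles)) {
    th <- par_angles[j]
    if (moving) {
      a <- alphas[j]
      xs <- X + a * Dx
      ys <- Y + a * Dy
    } else {
      xs <- X; ys <- Y
    }
    s <- xs * cos(th) + ys * sin(th)
    si <- (s - s0) / ds
    i0 <- floor(si)
    ok <- i0 >= 0 & i0 <= ns - 2
    dropped <- dropped + sum(!ok)
    i0ok <- as.integer(i0[ok])
    fr <- si[ok] - i0ok
    qw <- values[j, ] * weights[j, ]
    contrib <- numeric(length(si))
    contrib[ok] <- qw[i0ok + 1L] * (1 - fr) + qw[i0ok + 2L] * fr
    acc <- acc + contrib
  }
  list(values = acc * d_theta, dropped = dropped)
}

#' Weighted parallel-beam backprojection
#'
#' Accumulates `d_theta * sum_theta w(theta, s_x) * p_hat(theta, s_x)` with
#' `s_x = x . (cos theta, sin theta)` and linear interpolation in `s`.
#'
#' @param psino A ramp-filtered `parallel_sinogram`.
#' @param weights Weight matrix from [redundancy_weights()] (or uniform).
#' @param grid A [recon_grid()].
#' @param mu_water Water attenuation for HU metadata.
#' @return A [recon_image()].
#' @export
backproject <- function(psino, weights, grid, mu_water = 0.02) {
  stopifnot(inherits(psino, "parallel_sinogram"), inherits(grid, "recon_grid"),
            all(dim(weights) == dim(psino$values)))
  bp <- backproject_core(psino$values, weights, psino$par_angles,
                         psino$radial, grid)
  recon_image(bp$values, grid, mu_water = mu_water,
              time = psino$window$target_time %||% NA_real_,
              phase = psino$window$target_phase %||% NA_real_)
}

#' Conjugate partial-angle reconstruction
#'
#' Backprojects only the first (or last) `par_angle` of parallel view angles
#' in the gating window, with uniform weight inside the span (PAR images are
#' edge-feature images for registration, not quantitative reconstructions).
#' The two results are conjugate: their angular centres differ by pi and
#' their centre times by half the rotation time.
#'
#' @param psino A ramp-filtered `parallel_sinogram`.
#' @param grid A [recon_grid()].
#' @param which `"first"` or `"last"`.
#' @param par_angle Angular span, radians (default: the fan angle).
#' @param mu_water Water attenuation for HU metadata.
#' @return An object of class `par_image`: a [recon_image()] plus
#'   `angular_center`, `angular_halfwidth`, `center_time`.
#' @export
reconstruct_par <- function(psino, grid, which = c("first", "last"),
                            par_angle = psino$geometry$fan_angle_rad,
                            mu_water = 0.02) {
  which <- match.arg(which)
  stopifnot(inherits(psino, "parallel_sinogram"))
  th <- psino$par_angles
  span <- th[length(th)] - th[1]
  if (par_angle > span + 1e-9)
    stop("requested PAR span exceeds the gating window")
  n_rows <- round(par_angle / (th[2] - th[1])) + 1
  rows <- if (which == "first") 1:n_rows
          else (length(th) - n_rows + 1):length(th)
  w <- matrix(1, length(rows), length(psino$radial))
  bp <- backproject_core(psino$values[rows, , drop = FALSE], w,
                         th[rows], psino$radial, grid)
  img <- recon_image(bp$values, grid, mu_water = mu_water,
                     time = mean(psino$row_times[rows]))
  structure(list(image = img,
                 angular_center = mean(th[rows]),
                 angular_halfwidth = (th[rows[length(rows)]] - th[rows[1]]) / 2,
                 center_time = mean(psino$row_times[rows]),
                 rows = rows),
            class = "par_image")
}

#' Full filtered-backprojection reconstruction at a cardiac phase
#'
#' Convenience wrapper: gating-window selection, fan-to-parallel rebinning,
#' Ram-Lak filtering, short-scan redundancy weighting and backprojection.
#' This is the uncorrected (FBP) baseline the motion-compensated
#' reconstruction is compared against.
#'
#' @param fan_sino A `fan_sinogram` (carries its `ecg`).
#' @param target_phase R-R fraction.
#' @param grid A [recon_grid()].
#' @param cycle_index Cardiac cycle to reconstruct.
#' @param apodization Passed to [ramp_filter()].
#' @param mu_water Water attenuation reference, mm^-1.
#' @return A [recon_image()].
#' @export
fbp_reconstruct <- function(fan_sino, target_phase, grid, cycle_index = 0,
                            apodization = "none", mu_water = 0.02) {
  w <- select_gating_window(fan_sino$timeline, fan_sino$ecg, target_phase,
                            fan_sino$geometry, cycle_index)
  ps <- ramp_filter(rebin(fan_sino, w), apodization)
  backproject(ps, redundancy_weights(ps), grid, mu_water = mu_water)
}
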
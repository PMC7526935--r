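#' Time-varying analytic primitive
#'
#' A 2D primitive (ellipse/disk or concentric elliptical annulus) whose
#' geometric parameters are functions of cardiac phase. Constant parameters
#' may be given as plain numerics. All parameter functions must be continuous
#' and periodic in phase; the phantom machinery evaluates them via
#' [snapshot()].
#'
#' @param label Name of the structure (e.g. `"RCA"`).
#' @param shape `"ellipse"` (a disk is an ellipse with equal semi-axes),
#'   `"annulus"` (concentric inner/outer ellipses, attenuating in the band),
#'   or `"notched_rod"` (a disk carrying a fully interior low-density
#'   inclusion, the 2D cross-section of a stenosed artery rod).
#' @param mu Linear attenuation inside the primitive, mm^-1 (>= 0).
#' @param center Length-2 numeric or `function(phase)` returning (x, y) mm.
#' @param semi_axes Length-2 numeric or `function(phase)`; outer semi-axes mm.
#' @param tilt Numeric or `function(phase)`; rotation of the axes, radians.
#' @param inner_semi_axes For `"annulus"`: inner semi-axes, numeric or
#'   function of phase.
#' @param notch_center,notch_semi_axes,notch_mu For `"notched_rod"`: centre
#'   (numeric or function of phase), semi-axes and attenuation of the
#'   interior inclusion, which must stay fully inside the rod at all phases.
#' @param amplitude Optional declared bound (mm) on the displacement of the
#'   centre over the cycle; checked by property tests.
#' @return An object of class `tv_primitive`.
#' @export
tv_primitive <- function(label, shape = c("ellipse", "annulus", "notched_rod"),
                         mu, center, semi_axes, tilt = 0,
                         inner_semi_axes = NULL,
                         notch_center = NULL, notch_semi_axes = NULL,
                         notch_mu = 0, amplitude = NA_real_) {
  shape <- match.arg(shape)
  as_fn2 <- function(v) if (is.function(v)) v else {
    force(v); function(phase) v
  }
  if (shape == "annulus" && is.null(inner_semi_axes))
    stop("annulus needs inner_semi_axes")
  if (shape == "notched_rod" && (is.null(notch_center) || is.null(notch_semi_axes)))
    stop("notched_rod needs notch_center and notch_semi_axes")
  structure(list(label = label, shape = shape, mu = mu,
                 center = as_fn2(center), semi_axes = as_fn2(semi_axes),
                 tilt = as_fn2(tilt),
                 inner_semi_axes = if (is.null(inner_semi_axes)) NULL
                                   else as_fn2(inner_semi_axes),
                 notch_center = if (is.null(notch_center)) NULL
                                else as_fn2(notch_center),
                 notch_semi_axes = if (is.null(notch_semi_axes)) NULL
                                   else as_fn2(notch_semi_axes),
                 notch_mu = notch_mu,
                 amplitude = amplitude),
            class = "tv_primitive")
}

#' Dynamic phantom
#'
#' An ordered list of [tv_primitive()]s driven by an [ecg_model()]. Later
#' primitives are painted over earlier ones where they overlap; presets are
#' constructed strictly nested so analytic projection stays exact.
#'
#' @param primitives List of [tv_primitive()]s, painting order.
#' @param ecg An [ecg_model()].
#' @param fov_extent Diameter (mm) of the disc all primitives stay inside.
#' @return An object of class `dynamic_phantom`.
#' @export
dynamic_phantom <- function(primitives, ecg, fov_extent) {
  stopifnot(inherits(ecg, "ecg_model"), fov_extent > 0,
            all(vapply(primitives, inherits, TRUE, "tv_primitive")))
  structure(list(primitives = primitives, ecg = ecg,
                 fov_extent = fov_extent),
            class = "dynamic_phantom")
}

#' @export
print.dynamic_phantom <- function(x, ...) {
  cat(sprintf("<dynamic_phantom> %d primitives, %.0f bpm, FOV extent %.0f mm\n",
              length(x$primitives), x$ecg$heart_rate, x$fov_extent))
  for (p in x$primitives)
    cat(sprintf("  %-12s %-8s mu=%.4f mm^-1\n", p$label, p$shape, p$mu))
  invisible(x)
}

# ---- frozen (single time point) geometry -----------------------------------

# is point set (x, y) inside the *covered region* of a frozen primitive?
# (for notched_rod the covered region is the full outer disk; the notch only
# changes the painted value, not the coverage)
inside_frozen <- function(fp, x, y) {
  ct <- cos(fp$tilt); st <- sin(fp$tilt)
  dx <- x - fp$center[1]; dy <- y - fp$center[2]
  u <- ct * dx + st * dy; v <- -st * dx + ct * dy
  ins <- (u / fp$semi_axes[1])^2 + (v / fp$semi_axes[2])^2 <= 1
  if (fp$shape == "annulus") {
    hole <- (u / fp$inner_semi_axes[1])^2 + (v / fp$inner_semi_axes[2])^2 < 1
    ins & !hole
  } else ins
}

inside_ellipse <- function(center, semi, tilt, x, y) {
  ct <- cos(tilt); st <- sin(tilt)
  dx <- x - center[1]; dy <- y - center[2]
  u <- ct * dx + st * dy; v <- -st * dx + ct * dy
  (u / semi[1])^2 + (v / semi[2])^2 <= 1
}

# sample points characterising a frozen primitive's region (boundaries +
# centre line) for containment testing
region_samples <- function(fp, n = 48) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  ct <- cos(fp$tilt); st <- sin(fp$tilt)
  ring <- function(semi, shrink = 1) {
    u <- semi[1] * shrink * cos(th); v <- semi[2] * shrink * sin(th)
    cbind(fp$center[1] + ct * u - st * v, fp$center[2] + st * u + ct * v)
  }
  pts <- rbind(ring(fp$semi_axes, 0.999))
  if (fp$shape == "annulus") {
    pts <- rbind(pts, ring(fp$inner_semi_axes, 1.001),
                 ring((fp$semi_axes + fp$inner_semi_axes) / 2))
  } else {
    pts <- rbind(pts, ring(fp$semi_axes, 0.5), matrix(fp$center, 1))
  }
  pts
}

covers_frozen <- function(fa, fb) {
  p <- region_samples(fb)
  all(inside_frozen(fa, p[, 1], p[, 2]))
}

touches_frozen <- function(fa, fb) {
  p <- region_samples(fb)
  any(inside_frozen(fa, p[, 1], p[, 2]))
}

#' Freeze a dynamic phantom at a time point
#'
#' Evaluates every primitive's parameter functions at the cardiac phase of
#' `t` and resolves the painting order into an additive decomposition: each
#' frozen primitive gets `mu_add = mu - mu(parent)`, its parent being the
#' last earlier primitive fully covering it (air, mu 0, if none). Partial
#' overlaps between non-nested primitives are rejected — presets are built
#' strictly nested so that analytic line integrals remain exact.
#'
#' @param phantom A [dynamic_phantom()].
#' @param t Time, seconds (finite).
#' @return List of frozen primitives (class `frozen_phantom`), each with
#'   `center`, `semi_axes`, `tilt`, `inner_semi_axes`, `mu`, `mu_add`.
#' @export
snapshot <- function(phantom, t) {
  stopifnot(inherits(phantom, "dynamic_phantom"), is.finite(t))
  ph <- cardiac_phase(phantom$ecg, t)
  fr <- lapply(phantom$primitives, function(p) {
    f <- list(label = p$label, shape = p$shape, mu = p$mu,
              center = as.numeric(p$center(ph)),
              semi_axes = as.numeric(p$semi_axes(ph)),
              tilt = as.numeric(p$tilt(ph)))
    f$inner_semi_axes <- if (p$shape == "annulus")
      as.numeric(p$inner_semi_axes(ph)) else NULL
    if (p$shape == "notched_rod") {
      f$notch_center <- as.numeric(p$notch_center(ph))
      f$notch_semi_axes <- as.numeric(p$notch_semi_axes(ph))
      f$notch_mu <- p$notch_mu
      # the inclusion must stay strictly inside the rod
      th <- seq(0, 2 * pi, length.out = 25)[-25]
      bx <- f$notch_center[1] + f$notch_semi_axes[1] * cos(th)
      by <- f$notch_center[2] + f$notch_semi_axes[2] * sin(th)
      if (!all(inside_ellipse(f$center, f$semi_axes, f$tilt, bx, by)))
        stop(sprintf("notch of '%s' leaves the rod at phase %.3f", p$label, ph))
    }
    if (any(f$semi_axes <= 0) ||
        (p$shape == "annulus" && any(f$inner_semi_axes <= 0)))
      stop(sprintf("primitive '%s' has non-positive semi-axes at phase %.3f",
                   p$label, ph))
    f
  })
  n <- length(fr)
  for (j in seq_len(n)) {
    parent_mu <- 0
    if (j > 1) {
      for (i in rev(seq_len(j - 1))) {
        if (covers_frozen(fr[[i]], fr[[j]])) { parent_mu <- fr[[i]]$mu; break }
        if (touches_frozen(fr[[i]], fr[[j]]) || touches_frozen(fr[[j]], fr[[i]]))
          stop(sprintf(
            "primitives '%s' and '%s' partially overlap at phase %.3f; only nested overlap is supported",
            fr[[i]]$label, fr[[j]]$label, ph))
      }
    }
    fr[[j]]$mu_add <- fr[[j]]$mu - parent_mu
  }
  structure(fr, class = "frozen_phantom", phase = ph, time = t)
}

#' Rasterize a frozen phantom onto a grid
#'
#' Pixel value is the attenuation of the last covering primitive (painting
#' order), 0 where none covers. Sampled at pixel centres by default; with
#' `supersample = k` each pixel is averaged over a k x k sub-grid, reducing
#' partial-volume bias in ground-truth images used for metrics.
#'
#' @param frozen A [snapshot()] result (or a `dynamic_phantom` plus `t`).
#' @param grid A [recon_grid()].
#' @param supersample Integer >= 1, sub-samples per pixel side.
#' @param mu_water Water reference for the resulting image's HU metadata.
#' @return A [recon_image()].
#' @export
rasterize <- function(frozen, grid, supersample = 1, mu_water = 0.02) {
  stopifnot(inherits(grid, "recon_grid"), supersample >= 1)
  k <- as.integer(supersample)
  n <- grid$n
  if (k == 1) {
    xs <- grid$centers
  } else {
    off <- ((0:(k - 1)) + 0.5) / k - 0.5
    xs <- as.vector(outer(off * grid$pixel_size, grid$centers, "+"))
  }
  X <- matrix(xs, length(xs), length(xs))
  Y <- t(X)
  V <- matrix(0, length(xs), length(xs))
  for (fp in frozen) {
    ins <- inside_frozen(fp, X, Y)
    V[ins] <- fp$mu
    if (fp$shape == "notched_rod") {
      nin <- inside_ellipse(fp$notch_center, fp$notch_semi_axes, 0, X, Y)
      V[nin] <- fp$notch_mu
    }
  }
  if (k > 1) {
    # average k x k blocks (colMeans over the leading sub-sample dimension)
    V <- colMeans(array(V, dim = c(k, n, k * n)))        # n x (k*n)
    V <- t(colMeans(array(t(V), dim = c(k, n, n))))      # n x n
  }
  recon_image(V, grid, mu_water = mu_water,
              time = attr(frozen, "time") %||% NA_real_,
              phase = attr(frozen, "phase") %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
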
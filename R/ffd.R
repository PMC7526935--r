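#' Cubic B-spline free-form deformation field
#'
#' A displacement field parameterised by a uniform grid of control-point
#' displacements interpolated with cubic B-splines. Control point `(k, l)`
#' (0-based) sits at `origin + (k, l) * spacing`; a point influences and is
#' influenced by its 4 x 4 control neighbourhood only. The field maps
#' positions in the `t_start` frame to the `t_end` frame.
#'
#' @param controls `gx x gy x 2` array of control displacements, mm.
#' @param spacing Control grid spacing, mm.
#' @param origin Position of control (0, 0), mm (length 2).
#' @param t_start,t_end Times of the two frames the field connects, seconds.
#' @param displacement_cap Hard bound on evaluated displacement magnitude,
#'   mm (default 14.3, the assumed maximum structure displacement per half
#'   rotation).
#' @param diagnostics Optional registration diagnostics list.
#' @return An object of class `motion_vector_field`.
#' @export
motion_vector_field <- function(controls, spacing, origin,
                                t_start = NA_real_, t_end = NA_real_,
                                displacement_cap = 14.3,
                                diagnostics = list()) {
  stopifnot(length(dim(controls)) == 3, dim(controls)[3] == 2, spacing > 0)
  structure(list(controls = controls, spacing = spacing, origin = origin,
                 t_start = t_start, t_end = t_end,
                 displacement_cap = displacement_cap,
                 diagnostics = diagnostics),
            class = "motion_vector_field")
}

#' @export
print.motion_vector_field <- function(x, ...) {
  d <- dim(x$controls)
  cat(sprintf("<motion_vector_field> %d x %d control points, %.1f mm spacing\n",
              d[1], d[2], x$spacing))
  mag <- sqrt(x$controls[, , 1]^2 + x$controls[, , 2]^2)
  cat(sprintf("  max |control| %.2f mm, cap %.1f mm, t = [%.4f, %.4f] s\n",
              max(mag), x$displacement_cap, x$t_start, x$t_end))
  invisible(x)
}

#' Control-point displacements of a motion field
#'
#' @param object A `motion_vector_field`.
#' @param ... Unused.
#' @return The `gx x gy x 2` control-displacement array (mm).
#' @export
coef.motion_vector_field <- function(object, ...) object$controls

# cubic B-spline weights for fractional coordinate u (vectorised): returns
# i0 = floor(u) and the 4 weights for controls i0-1 .. i0+2
bspline_w <- function(u) {
  i0 <- floor(u)
  t <- u - i0
  t2 <- t * t; t3 <- t2 * t
  list(i0 = as.integer(i0),
       w = cbind((1 - t)^3, 3 * t3 - 6 * t2 + 4,
                 -3 * t3 + 3 * t2 + 3 * t + 1, t3) / 6)
}

# sparse-banded basis matrix mapping control coefficients (gx) to values at
# coordinates xs (mm): B[i, k] = B3((xs[i]-origin)/h - (k-1))
bspline_basis <- function(xs, origin, spacing, g) {
  u <- (xs - origin) / spacing
  bw <- bspline_w(u)
  B <- matrix(0, length(xs), g)
  for (a in 0:3) {
    k <- bw$i0 - 1L + a
    ok <- k >= 0 & k <= g - 1
    B[cbind(which(ok), k[ok] + 1L)] <- bw$w[ok, a + 1]
  }
  B
}

#' Dense evaluation of a motion field on a tensor grid
#'
#' Evaluates the B-spline field's x/y displacement components at all
#' combinations of `xs` and `ys` via separable basis matrices.
#'
#' @param mvf A [motion_vector_field()].
#' @param xs,ys Coordinates in mm.
#' @return List with matrices `Dx`, `Dy` (`length(xs) x length(ys)`, mm).
#' @export
ffd_dense <- function(mvf, xs, ys) {
  d <- dim(mvf$controls)
  BX <- bspline_basis(xs, mvf$origin[1], mvf$spacing, d[1])
  BY <- bspline_basis(ys, mvf$origin[2], mvf$spacing, d[2])
  list(Dx = BX %*% mvf$controls[, , 1] %*% t(BY),
       Dy = BX %*% mvf$controls[, , 2] %*% t(BY))
}

#' Evaluate a free-form deformation at points
#'
#' Cubic B-spline tensor interpolation of the control displacements. Points
#' outside the control grid's valid support are clamped to it with a
#' warning.
#'
#' @param mvf A [motion_vector_field()].
#' @param points `n x 2` matrix of (x, y) positions, mm.
#' @return `n x 2` matrix of displacements, mm.
#' @export
ffd_displace <- function(mvf, points) {
  points <- rbind(points)
  d <- dim(mvf$controls)
  u <- (points[, 1] - mvf$origin[1]) / mvf$spacing
  v <- (points[, 2] - mvf$origin[2]) / mvf$spacing
  ulim <- c(1, d[1] - 3); vlim <- c(1, d[2] - 3)
  if (any(u < ulim[1] | u > ulim[2] + 1 | v < vlim[1] | v > vlim[2] + 1))
    warning("points outside the deformation extent were clamped")
  # clamp (also folds the exact upper support edge onto the last valid span)
  u <- pmin(pmax(u, ulim[1]), ulim[2] + 1 - 1e-9)
  v <- pmin(pmax(v, vlim[1]), vlim[2] + 1 - 1e-9)
  bu <- bspline_w(u); bv <- bspline_w(v)
  out <- matrix(0, length(u), 2)
  Cx <- mvf$controls[, , 1]; Cy <- mvf$controls[, , 2]
  for (a in 0:3) for (b in 0:3) {
    idx <- cbind(bu$i0 + a, bv$i0 + b)   # 1-based: (i0-1+a)+1
    wab <- bu$w[, a + 1] * bv$w[, b + 1]
    out[, 1] <- out[, 1] + wab * Cx[idx]
    out[, 2] <- out[, 2] + wab * Cy[idx]
  }
  out
}

#' Predict displacements from a motion field
#'
#' Evaluates the field at points, optionally scaled to an intermediate time
#' by the linear motion model (see [temporal_scale()]).
#'
#' @param object A `motion_vector_field`.
#' @param points `n x 2` matrix of positions (mm).
#' @param t Optional time (s); if given, displacements are scaled by
#'   `(t - target_time) / (t_end - t_start)` with the target at the
#'   midpoint.
#' @param ... Unused.
#' @return `n x 2` displacement matrix (mm).
#' @export
predict.motion_vector_field <- function(object, points, t = NULL, ...) {
  d <- ffd_displace(object, points)
  if (!is.null(t)) {
    target <- (object$t_start + object$t_end) / 2
    d <- d * (t - target) / (object$t_end - object$t_start)
  }
  d
}

#' Plot a motion field as arrows
#'
#' @param x A `motion_vector_field`.
#' @param scale Arrow length multiplier.
#' @param ... Passed to [graphics::arrows()].
#' @export
plot.motion_vector_field <- function(x, scale = 1, ...) {
  d <- dim(x$controls)
  px <- x$origin[1] + (0:(d[1] - 1)) * x$spacing
  py <- x$origin[2] + (0:(d[2] - 1)) * x$spacing
  X <- matrix(px, d[1], d[2]); Y <- matrix(py, d[1], d[2], byrow = TRUE)
  graphics::plot(X, Y, pch = ".", asp = 1, xlab = "x (mm)", ylab = "y (mm)")
  dx <- x$controls[, , 1] * scale; dy <- x$controls[, , 2] * scale
  keep <- sqrt(dx^2 + dy^2) > 1e-6
  if (any(keep))
    graphics::arrows(X[keep], Y[keep], X[keep] + dx[keep], Y[keep] + dy[keep],
                     length = 0.03, ...)
  invisible(x)
}
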
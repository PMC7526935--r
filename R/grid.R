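#' Reconstruction grid
#'
#' A square pixel grid centred on the scanner isocenter. Pixel centres sit at
#' `(i + 0.5 - n/2) * pixel_size` for 0-based index `i`, so the grid is
#' symmetric about the origin and the field of view is `n * pixel_size` mm.
#'
#' @param n Pixels per side.
#' @param pixel_size Pixel size in mm.
#' @return An object of class `recon_grid` with elements `n`, `pixel_size`,
#'   `centers` (pixel-centre coordinates, mm) and `fov` (mm).
#' @export
recon_grid <- function(n, pixel_size) {
  stopifnot(n >= 2, pixel_size > 0)
  centers <- ((0:(n - 1)) + 0.5 - n / 2) * pixel_size
  structure(list(n = as.integer(n), pixel_size = pixel_size,
                 centers = centers, fov = n * pixel_size),
            class = "recon_grid")
}

#' Reconstruction image container
#'
#' Holds attenuation values (mm^-1) on a [recon_grid()] plus the water
#' attenuation used for Hounsfield conversion and, optionally, the time and
#' cardiac phase the image represents.
#'
#' @param values `n x n` matrix of linear attenuation, mm^-1; `values[i, j]`
#'   is the pixel at x-index `i`, y-index `j`.
#' @param grid A [recon_grid()].
#' @param mu_water Water attenuation reference, mm^-1 (default 0.02).
#' @param time,phase Optional target time (s) and cardiac phase of the image.
#' @return An object of class `recon_image`.
#' @export
recon_image <- function(values, grid, mu_water = 0.02, time = NA_real_,
                        phase = NA_real_) {
  stopifnot(inherits(grid, "recon_grid"),
            is.matrix(values), all(dim(values) == grid$n))
  structure(list(values = values, grid = grid, mu_water = mu_water,
                 time = time, phase = phase),
            class = "recon_image")
}

#' Convert between linear attenuation and Hounsfield units
#'
#' `HU = 1000 * (mu - mu_water) / mu_water`, so water maps to 0 HU and air
#' (mu = 0) to -1000 HU.
#'
#' @param mu Attenuation, mm^-1 (vector/matrix).
#' @param hu Hounsfield units (vector/matrix).
#' @param mu_water Water reference attenuation, mm^-1.
#' @return The converted values.
#' @export
mu_to_hu <- function(mu, mu_water = 0.02) 1000 * (mu - mu_water) / mu_water

#' @rdname mu_to_hu
#' @export
hu_to_mu <- function(hu, mu_water = 0.02) mu_water * (1 + hu / 1000)

#' @export
print.recon_image <- function(x, ...) {
  cat(sprintf("<recon_image> %d x %d pixels, %.3f mm/px, FOV %.1f mm\n",
              x$grid$n, x$grid$n, x$grid$pixel_size, x$grid$fov))
  cat(sprintf("  mu range [%.5f, %.5f] mm^-1  (HU [%.0f, %.0f])\n",
              min(x$values), max(x$values),
              mu_to_hu(min(x$values), x$mu_water),
              mu_to_hu(max(x$values), x$mu_water)))
  if (is.finite(x$time)) cat(sprintf("  target time %.4f s, phase %.3f\n", x$time, x$phase))
  invisible(x)
}

#' Display a reconstruction image
#'
#' @param x A `recon_image`.
#' @param hu Display in Hounsfield units (default) rather than mm^-1.
#' @param ... Passed to [graphics::image()].
#' @export
plot.recon_image <- function(x, hu = TRUE, ...) {
  v <- if (hu) mu_to_hu(x$values, x$mu_water) else x$values
  graphics::image(x$grid$centers, x$grid$centers, v, asp = 1,
                  col = grDevices::gray.colors(256, 0, 1),
                  xlab = "x (mm)", ylab = "y (mm)", ...)
  invisible(x)
}

#' Sample an image at arbitrary positions
#'
#' Bilinear interpolation of a [recon_image()] at (x, y) positions in mm
#' (vectorised; points outside the grid are clamped to the border).
#'
#' @param img A [recon_image()].
#' @param x,y Coordinates in mm.
#' @return Sampled attenuation values, mm^-1 (same shape as `x`).
#' @export
sample_image <- function(img, x, y) {
  g <- img$grid
  bilinear_mat(img$values, (x - g$centers[1]) / g$pixel_size,
               (y - g$centers[1]) / g$pixel_size)
}

# Bilinear interpolation on a matrix at fractional 0-based indices (ix, iy),
# clamped to the valid range.
bilinear_mat <- function(m, ix, iy) {
  nx <- nrow(m); ny <- ncol(m)
  ix <- pmin(pmax(ix, 0), nx - 1)
  iy <- pmin(pmax(iy, 0), ny - 1)
  i0 <- pmin(floor(ix), nx - 2); j0 <- pmin(floor(iy), ny - 2)
  fx <- ix - i0; fy <- iy - j0
  i0 <- as.integer(i0); j0 <- as.integer(j0)
  v00 <- m[cbind(i0 + 1L, j0 + 1L)]
  v10 <- m[cbind(i0 + 2L, j0 + 1L)]
  v01 <- m[cbind(i0 + 1L, j0 + 2L)]
  v11 <- m[cbind(i0 + 2L, j0 + 2L)]
  v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
    v01 * (1 - fx) * fy + v11 * fx * fy
}
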
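#' Rectangular region of interest
#'
#' @param center (x, y) centre, mm.
#' @param half_extent Half side length, mm (default 10, i.e. a 20 x 20 mm
#'   ROI around a coronary-artery analog).
#' @param label Structure label (e.g. `"RCA"`).
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(center, half_extent = 10, label = "") {
  stopifnot(length(center) == 2, half_extent > 0)
  structure(list(center = center, half_extent = half_extent, label = label),
            class = "roi_spec")
}

roi_indices <- function(img, roi) {
  g <- img$grid
  ix <- which(abs(g$centers - roi$center[1]) <= roi$half_extent)
  iy <- which(abs(g$centers - roi$center[2]) <= roi$half_extent)
  if (length(ix) == 0 || length(iy) == 0 ||
      roi$center[1] - roi$half_extent < g$centers[1] - g$pixel_size / 2 ||
      roi$center[1] + roi$half_extent > g$centers[g$n] + g$pixel_size / 2 ||
      roi$center[2] - roi$half_extent < g$centers[1] - g$pixel_size / 2 ||
      roi$center[2] + roi$half_extent > g$centers[g$n] + g$pixel_size / 2)
    stop("ROI outside the image FOV")
  list(ix = ix, iy = iy)
}

# separable "valid" convolution with a 1D kernel along both axes
conv2_valid <- function(m, k) {
  w <- length(k)
  n1 <- nrow(m) - w + 1; n2 <- ncol(m) - w + 1
  if (n1 < 1 || n2 < 1) stop("region smaller than the SSIM window")
  K1 <- matrix(0, n1, nrow(m))
  K1[cbind(rep(1:n1, each = w), as.vector(t(outer(1:n1, 0:(w - 1), "+"))))] <- k
  K2 <- matrix(0, n2, ncol(m))
  K2[cbind(rep(1:n2, each = w), as.vector(t(outer(1:n2, 0:(w - 1), "+"))))] <- k
  K1 %*% m %*% t(K2)
}

#' Mean structural similarity over an ROI
#'
#' The classical SSIM map — the luminance/contrast/structure product with
#' stabilizers `C1 = (K1*L)^2`, `C2 = (K2*L)^2` and an 11 x 11 Gaussian
#' window (sigma 1.5) — averaged over the ROI. Because these are HU images
#' rather than 8-bit data, the dynamic range `L` is taken from the
#' reference ROI (max - min) by default.
#'
#' @param img,ref [recon_image()]s on the same grid (`ref` is the ground
#'   truth).
#' @param roi A [roi_spec()]; `NULL` uses the whole image.
#' @param K1,K2 Stabilizer constants (defaults 0.01, 0.03).
#' @param L Dynamic range; default `max - min` of the reference ROI in HU.
#' @param window_size,sigma Gaussian window parameters (11, 1.5).
#' @return MSSIM in `[-1, 1]`.
#' @export
mssim <- function(img, ref, roi = NULL, K1 = 0.01, K2 = 0.03, L = NULL,
                  window_size = 11, sigma = 1.5) {
  stopifnot(inherits(img, "recon_image"), inherits(ref, "recon_image"),
            img$grid$n == ref$grid$n)
  if (is.null(roi)) {
    a <- mu_to_hu(img$values, img$mu_water)
    b <- mu_to_hu(ref$values, ref$mu_water)
  } else {
    id <- roi_indices(ref, roi)
    a <- mu_to_hu(img$values[id$ix, id$iy], img$mu_water)
    b <- mu_to_hu(ref$values[id$ix, id$iy], ref$mu_water)
  }
  if (is.null(L)) L <- max(b) - min(b)
  if (L <= 0) L <- 1
  r <- (window_size - 1) / 2
  k <- exp(-((-r):r)^2 / (2 * sigma^2)); k <- k / sum(k)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  mu1 <- conv2_valid(a, k); mu2 <- conv2_valid(b, k)
  s11 <- conv2_valid(a * a, k) - mu1^2
  s22 <- conv2_valid(b * b, k) - mu2^2
  s12 <- conv2_valid(a * b, k) - mu1 * mu2
  ssim_map <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  mean(ssim_map)
}

#' Root mean square error in Hounsfield units
#'
#' @param img,ref [recon_image()]s on the same grid.
#' @param mask Logical matrix selecting pixels (`NULL` = whole image), or a
#'   [roi_spec()].
#' @return RMSE in HU (>= 0).
#' @export
rmse_hu <- function(img, ref, mask = NULL) {
  stopifnot(inherits(img, "recon_image"), inherits(ref, "recon_image"),
            img$grid$n == ref$grid$n)
  d <- mu_to_hu(img$values, img$mu_water) - mu_to_hu(ref$values, ref$mu_water)
  if (inherits(mask, "roi_spec")) {
    id <- roi_indices(ref, mask)
    d <- d[id$ix, id$iy]
  } else if (!is.null(mask)) {
    if (!any(mask)) stop("empty mask")
    d <- d[mask]
  }
  sqrt(mean(d^2))
}

#' Line profile through an image
#'
#' @param img A [recon_image()].
#' @param from,to Endpoints (x, y), mm; must lie inside the FOV.
#' @param n_samples Number of samples along the segment.
#' @return Numeric vector of HU values (bilinear interpolation).
#' @export
line_profile <- function(img, from, to, n_samples = 50) {
  g <- img$grid
  half <- g$fov / 2
  if (any(abs(c(from, to)) > half))
    stop("profile endpoints outside the FOV")
  t <- seq(0, 1, length.out = n_samples)
  x <- from[1] + t * (to[1] - from[1])
  y <- from[2] + t * (to[2] - from[2])
  mu_to_hu(sample_image(img, x, y), img$mu_water)
}

#' HU stability of a line profile across cardiac phases
#'
#' Samples each per-phase image along the same segment, pools all samples
#' and returns the population standard deviation: a single-number summary
#' of how stable a uniform myocardial-wall region stays across the R-R
#' cycle (lower is better).
#'
#' @param images List (length >= 2) of [recon_image()]s, one per phase.
#' @param from,to Profile endpoints, mm.
#' @param n_samples Samples per profile.
#' @return List with `std` (pooled population SD, HU) and `profiles`
#'   (matrix `n_samples x n_phases`, for plotting).
#' @export
profile_stability <- function(images, from, to, n_samples = 50) {
  if (length(images) < 2) stop("need images at two or more phases")
  profs <- vapply(images, line_profile, numeric(n_samples),
                  from = from, to = to, n_samples = n_samples)
  v <- as.vector(profs)
  list(std = sqrt(mean((v - mean(v))^2)), profiles = profs)
}

#' One-sided paired t-test
#'
#' Direct textbook implementation: `t = mean(d) / (sd(d)/sqrt(n))` on the
#' paired differences, compared against the t distribution with `n - 1`
#' degrees of freedom. With `alternative = "greater"` the p-value is small
#' when `a` systematically exceeds `b`. Zero-variance, nonzero-mean
#' differences give p of 0 or 1 with a degenerate flag; all-zero
#' differences give t = 0, hence p = 0.5.
#'
#' @param a,b Equal-length paired samples (n >= 2).
#' @param alternative `"greater"` (default) or `"less"`.
#' @return List with `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
paired_compare <- function(a, b, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(a) != length(b) || length(a) < 2)
    stop("need equal-length paired samples with n >= 2")
  d <- a - b
  n <- length(d)
  s <- stats::sd(d)
  if (s == 0) {
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (alternative == "greater") stats::pt(t_stat, n - 1, lower.tail = FALSE)
         else stats::pt(t_stat, n - 1)
    return(list(t = t_stat, df = n - 1, p = p, mean_diff = mean(d),
                degenerate = TRUE))
  }
  t_stat <- mean(d) / (s / sqrt(n))
  p <- if (alternative == "greater") stats::pt(t_stat, n - 1, lower.tail = FALSE)
       else stats::pt(t_stat, n - 1)
  list(t = t_stat, df = n - 1, p = p, mean_diff = mean(d), degenerate = FALSE)
}
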
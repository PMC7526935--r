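#' Radial band-pass edge extraction
#'
#' Isotropic frequency-domain band-pass applied to a square image: an
#' annular mask keeps normalized radial frequency in `[f_lo, f_hi]` (units
#' of pi rad/sample, Nyquist = 1) with raised-cosine transitions of width
#' `softness` times each cutoff; ideal (hard) masks ring. The mask is 0 at
#' DC, so the output has zero mean. On partial-angle reconstructions this
#' keeps edge information while discarding the low-frequency shading
#' artifacts of limited-angle backprojection.
#'
#' @param image A [recon_image()] or plain square matrix.
#' @param f_lo,f_hi Band edges in pi rad/sample (defaults 0.1 and 0.3).
#' @param softness Transition width as a fraction of each cutoff (default
#'   0.1).
#' @return Same type as `image`, band-pass filtered.
#' @export
bandpass <- function(image, f_lo = 0.1, f_hi = 0.3, softness = 0.1) {
  if (f_lo >= f_hi) stop("f_lo must be below f_hi")
  if (f_lo < 0 || f_hi > 1) stop("band edges must lie in [0, 1] (pi rad/sample)")
  m <- if (inherits(image, "recon_image")) image$values else image
  if (nrow(m) != ncol(m)) stop("bandpass expects a square image")
  n <- nrow(m)
  f1 <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n   # cycles/sample per bin
  nu <- 2 * sqrt(outer(f1^2, f1^2, "+"))             # pi rad/sample
  wlo <- softness * f_lo; whi <- softness * f_hi
  # transitions sit inside the band so the passband is strictly [f_lo, f_hi]
  mask <- matrix(0, n, n)
  rise <- nu > f_lo & nu < f_lo + wlo
  mask[rise] <- 0.5 * (1 - cos(pi * (nu[rise] - f_lo) / wlo))
  mask[nu >= f_lo + wlo & nu <= f_hi - whi] <- 1
  fall <- nu > f_hi - whi & nu < f_hi
  mask[fall] <- 0.5 * (1 + cos(pi * (nu[fall] - f_hi + whi) / whi))
  out <- Re(stats::fft(stats::fft(m) * mask, inverse = TRUE)) / length(m)
  if (inherits(image, "recon_image")) { image$values <- out; image }
  else out
}
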
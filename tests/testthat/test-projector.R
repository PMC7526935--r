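test_that("ray_for maps channels to in-fan angles symmetrically", {
  geo <- test_geometry()
  nc <- geo$n_channels
  central <- ray_for(geo, 0, (nc - 1) / 2)
  expect_equal(central$gamma, 0)
  expect_equal(central$s, 0)
  # central ray at view 0 passes through the isocenter
  tpar <- -sum(central$point * central$dir)
  expect_equal(central$point + tpar * central$dir, c(0, 0), tolerance = 1e-12)
  # symmetric channel pair mirrors about the central ray
  r1 <- ray_for(geo, 0, 0); r2 <- ray_for(geo, 0, nc - 1)
  expect_equal(r1$gamma, -r2$gamma)
  expect_equal(abs(r1$gamma), geo$fan_angle_rad / 2)
  expect_equal(r1$s, -r2$s)
  expect_error(ray_for(geo, 0, nc), "range")
})

test_that("line integrals match closed-form disk chords", {
  # ray through the centre of a disk: 2 r mu
  fp <- list(label = "d", shape = "ellipse", mu = 0.02,
             center = c(0, 0), semi_axes = c(10, 10), tilt = 0)
  ray <- list(point = c(-50, 0), dir = c(1, 0))
  expect_equal(primitive_line_integral(fp, ray), 0.4)
  # impact parameter 6: 2 mu sqrt(r^2 - s^2) = 0.32
  ray2 <- list(point = c(-50, 6), dir = c(1, 0))
  expect_equal(primitive_line_integral(fp, ray2), 2 * 0.02 * sqrt(100 - 36))
  # miss
  ray3 <- list(point = c(-50, 11), dir = c(1, 0))
  expect_equal(primitive_line_integral(fp, ray3), 0)
  # tilted ellipse equals rotated-frame computation
  fe <- list(label = "e", shape = "ellipse", mu = 0.01,
             center = c(5, -3), semi_axes = c(12, 4), tilt = 0.6)
  raya <- list(point = c(-80, -3), dir = c(cos(0.6), sin(0.6)))
  # along the tilted major axis through the centre: chord = 2 a
  raym <- list(point = fe$center - 100 * c(cos(0.6), sin(0.6)),
               dir = c(cos(0.6), sin(0.6)))
  expect_equal(primitive_line_integral(fe, raym), 2 * 12 * 0.01,
               tolerance = 1e-10)
})

test_that("forward projection of a static phantom is view-consistent", {
  geo <- test_geometry(184, 90)
  tl <- scan_timeline(geo, 1)
  p <- disk_phantom(r = 20, mu = 0.04, center = c(30, -10))
  sino <- forward_project(p, geo, tl)
  expect_true(all(sino$values >= 0))
  expect_true(all(is.finite(sino$values)))
  # zero phantom -> zero sinogram
  p0 <- dynamic_phantom(list(), ecg_model(60), fov_extent = 10)
  expect_equal(max(abs(forward_project(p0, geo, tl)$values)), 0)
  # each row equals the direct per-ray analytic integral
  v <- 23
  fr <- snapshot(p, tl$view_times[v])
  row <- vapply(0:(geo$n_channels - 1), function(k) {
    r <- ray_for(geo, tl$view_angles[v], k)
    primitive_line_integral(fr[[1]], r)
  }, numeric(1))
  expect_equal(sino$values[v, ], row, tolerance = 1e-12)
})

test_that("projection is linear in disjoint phantom unions", {
  geo <- test_geometry(184, 45)
  tl <- scan_timeline(geo, 1)
  pa <- disk_phantom(r = 15, mu = 0.03, center = c(40, 0))
  pb <- disk_phantom(r = 10, mu = 0.05, center = c(-40, 20))
  pab <- dynamic_phantom(c(pa$primitives, pb$primitives), ecg_model(60),
                         fov_extent = 160)
  sa <- forward_project(pa, geo, tl)$values
  sb <- forward_project(pb, geo, tl)$values
  sab <- forward_project(pab, geo, tl)$values
  expect_equal(sab, sa + sb, tolerance = 1e-12)
})

test_that("rotating a static phantom equals shifting view angles", {
  geo <- test_geometry(184, 90)
  d <- 2 * pi / 90 * 7   # rotate by exactly 7 view increments
  p1 <- disk_phantom(r = 18, mu = 0.03, center = c(35, 10))
  cen2 <- c(cos(d) * 35 - sin(d) * 10, sin(d) * 35 + cos(d) * 10)
  p2 <- disk_phantom(r = 18, mu = 0.03, center = cen2)
  tl <- scan_timeline(geo, 1)
  s1 <- forward_project(p1, geo, tl)$values
  s2 <- forward_project(p2, geo, tl)$values
  # row v of the rotated phantom equals row v - 7 of the original
  expect_equal(s2[8:90, ], s1[1:83, ], tolerance = 1e-9)
})

test_that("a translating disk's projection centroid follows its centre", {
  geo <- test_geometry(368, 180)
  tl <- scan_timeline(geo, 1)
  ecg <- ecg_model(60)
  ctr <- function(phase) c(-20 + 15 * tri_wave(phase), 10)
  p <- dynamic_phantom(list(
    tv_primitive("d", "ellipse", 0.05, ctr, c(8, 8), amplitude = 15)),
    ecg, fov_extent = 120)
  sino <- forward_project(p, geo, tl)
  dg <- geo$fan_angle_rad / (geo$n_channels - 1)
  gamma <- ((0:(geo$n_channels - 1)) - (geo$n_channels - 1) / 2) * dg
  for (v in c(10, 60, 120)) {
    w <- sino$values[v, ]
    g_cent <- sum(gamma * w) / sum(w)
    # expected gamma: signed CCW angle from the central ray (source ->
    # isocenter) to the source -> centre direction
    cen <- ctr(cardiac_phase(ecg, tl$view_times[v]))
    beta <- tl$view_angles[v]
    src <- geo$source_to_iso * c(-sin(beta), cos(beta))
    u <- -src; v2 <- cen - src
    gam_expect <- atan2(u[1] * v2[2] - u[2] * v2[1], sum(u * v2))
    # weighted centroid of a symmetric profile ~ centre's fan angle
    expect_lt(abs(g_cent - gam_expect), dg * 1.5)
  }
})

test_that("phantoms larger than the scan FOV are rejected", {
  geo <- test_geometry()
  tl <- scan_timeline(geo, 1)
  big <- dynamic_phantom(list(
    tv_primitive("b", "ellipse", 0.02, c(0, 0), c(260, 260))),
    ecg_model(60), fov_extent = 520)
  expect_error(forward_project(big, geo, tl), "FOV")
})

test_that("Poisson noise is seeded, unbiased and vanishes at high flux", {
  geo <- test_geometry(92, 24)
  tl <- scan_timeline(geo, 1)
  sino <- forward_project(disk_phantom(), geo, tl)
  n1 <- add_noise(sino, 1e4, seed = 11)
  n2 <- add_noise(sino, 1e4, seed = 11)
  expect_identical(n1$values, n2$values)
  n3 <- add_noise(sino, 1e4, seed = 12)
  expect_false(identical(n1$values, n3$values))
  # high flux limit
  hi <- add_noise(sino, 1e9, seed = 1)
  expect_equal(hi$values, sino$values, tolerance = 1e-3)
  expect_error(add_noise(sino, 0), "positive")
  # Monte-Carlo mean of one ray ~ true line integral within 3 SE
  p_true <- 0.8; N <- 2000; photons <- 1e4
  old <- .Random.seed
  set.seed(99)
  draws <- -log(pmax(stats::rpois(N, photons * exp(-p_true)), 1) / photons)
  .Random.seed <<- old
  se <- stats::sd(draws) / sqrt(N)
  expect_lt(abs(mean(draws) - p_true), 3 * se + 1e-6)
})

test_that("analytic projections agree with ray-marching the raster image", {
  geo <- test_geometry(184, 8)
  tl <- scan_timeline(geo, 1)
  p <- preset_phantom("static")
  sino <- forward_project(p, geo, tl)
  fr <- snapshot(p, 0)
  g <- recon_grid(1024, 410 / 1024)
  img <- rasterize(fr, g, supersample = 2)
  v <- 3
  beta <- tl$view_angles[v]
  src <- geo$source_to_iso * c(-sin(beta), cos(beta))
  step <- 0.25
  ts <- seq(geo$source_to_iso - 210, geo$source_to_iso + 210, by = step)
  marched <- vapply(seq(0, geo$n_channels - 1, by = 8), function(k) {
    r <- ray_for(geo, beta, k)
    xs <- src[1] + ts * r$dir[1]; ys <- src[2] + ts * r$dir[2]
    keep <- abs(xs) < 204 & abs(ys) < 204
    sum(sample_image(img, xs[keep], ys[keep])) * step
  }, numeric(1))
  analytic <- sino$values[v, seq(1, geo$n_channels, by = 8)]
  rel_rms <- sqrt(mean((marched - analytic)^2)) / max(analytic)
  expect_lt(rel_rms, 0.01)
})
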
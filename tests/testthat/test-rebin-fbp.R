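test_that("gating window has the short-scan-plus-fan width", {
  geo <- test_geometry()
  tl <- scan_timeline(geo, 2)
  ecg <- ecg_model(60)
  w <- select_gating_window(tl, ecg, 0.3, geo)
  # pi + 2 * 52 deg = 284 deg of tube angle
  expect_equal(w$width * 180 / pi, 284, tolerance = 1)
  # 0.25 s rotation -> ~0.1972 s of data
  dur <- tl$view_times[w$last] - tl$view_times[w$first]
  expect_equal(dur, (284 / 360) * 0.25, tolerance = 0.002)
  # centred on the target time
  expect_equal(tl$view_times[w$center], w$target_time, tolerance = tl$d_time)
  # target phase at an R peak maps to the R-peak time
  ecg_fast <- ecg_model(160)
  w0 <- select_gating_window(tl, ecg_fast, 0, geo, cycle_index = 1)
  expect_equal(w0$target_time, 60 / 160)
  # window exceeding the scan errors
  expect_error(select_gating_window(tl, ecg, 0.05, geo, cycle_index = 0),
               "exceeds")
  expect_error(select_gating_window(tl, ecg, 0.3, geo,
                                    width = 2 * pi), "less than")
})

test_that("rebinned rows of a static disk match the parallel projection", {
  geo <- test_geometry()
  tl <- scan_timeline(geo, 2)
  p <- disk_phantom(r = 40, mu = 0.02, center = c(0, 0))
  sino <- forward_project(p, geo, tl)
  w <- select_gating_window(tl, sino$ecg, 0.3, geo)
  ps <- rebin(sino, w)
  expected <- ifelse(abs(ps$radial) < 40,
                     2 * 0.02 * sqrt(pmax(40^2 - ps$radial^2, 0)), 0)
  for (j in c(1, nrow(ps$values) %/% 2, nrow(ps$values))) {
    rel <- max(abs(ps$values[j, ] - expected)) / max(expected)
    expect_lt(rel, 0.01)
  }
  # row times increase and match the view sampling rate
  expect_true(all(diff(ps$row_times) > 0))
  expect_equal(diff(ps$row_times)[1], tl$d_time, tolerance = 1e-12)
})

test_that("ramp filter basics", {
  geo <- test_geometry()
  tl <- scan_timeline(geo, 2)
  sino <- forward_project(disk_phantom(), geo, tl)
  w <- select_gating_window(tl, sino$ecg, 0.3, geo)
  ps <- rebin(sino, w)
  ps$values[5, ] <- 0          # zero row stays zero
  pf <- ramp_filter(ps)
  expect_equal(max(abs(pf$values[5, ])), 0)
  # constant (DC) row: near-zero response (small truncation leakage only)
  ps$values[7, ] <- 1
  pf <- ramp_filter(ps)
  expect_lt(abs(mean(pf$values[7, ])), 5e-3)
})

test_that("redundancy weights form a smooth partition over conjugate rays", {
  geo <- test_geometry()
  tl <- scan_timeline(geo, 2)
  sino <- forward_project(disk_phantom(), geo, tl)
  w <- select_gating_window(tl, sino$ecg, 0.3, geo)
  ps <- rebin(sino, w)
  wt <- redundancy_weights(ps)
  expect_true(all(wt >= 0 & wt <= 1))
  # conjugate pairs: theta_j and theta_j + pi
  m <- length(ps$par_angles)
  step <- round(pi / (ps$par_angles[2] - ps$par_angles[1]))
  j <- seq_len(m - step)
  expect_equal(wt[j, 1] + wt[j + step, 1], rep(1, length(j)), tolerance = 1e-9)
  # core rays measured once have weight 1
  core <- (ps$par_angles > ps$par_angles[m] - pi + 1e-9) &
          (ps$par_angles < ps$par_angles[1] + pi - 1e-9)
  expect_true(all(wt[core, ] == 1))
})

test_that("weighted FBP recovers attenuation of a static disk", {
  geo <- test_geometry()
  tl <- scan_timeline(geo, 2)
  p <- disk_phantom(r = 30, mu = 0.04, center = c(20, -15))
  sino <- forward_project(p, geo, tl)
  g <- test_grid(128)
  img <- fbp_reconstruct(sino, 0.3, g)
  # mean inside 80% radius within 2% of the true mu
  X <- matrix(g$centers, g$n, g$n); Y <- t(X)
  inside <- sqrt((X - 20)^2 + (Y + 15)^2) < 0.8 * 30
  expect_equal(mean(img$values[inside]), 0.04, tolerance = 0.02)
  # scaling linearity: doubling mu doubles the image
  p2 <- disk_phantom(r = 30, mu = 0.08, center = c(20, -15))
  img2 <- fbp_reconstruct(forward_project(p2, geo, tl), 0.3, g)
  expect_equal(img2$values, 2 * img$values, tolerance = 1e-10)
})

test_that("backprojection of a zero sinogram is zero and symmetry is kept", {
  geo <- test_geometry()
  tl <- scan_timeline(geo, 2)
  sino <- forward_project(disk_phantom(r = 30, mu = 0.04, center = c(0, 0)),
                          geo, tl)
  w <- select_gating_window(tl, sino$ecg, 0.3, geo)
  ps <- ramp_filter(rebin(sino, w))
  wt <- redundancy_weights(ps)
  g <- test_grid(64)
  ps0 <- ps; ps0$values[] <- 0
  expect_equal(backproject(ps0, wt, g)$values, matrix(0, 64, 64))
  # centred disk: reconstruction symmetric under point reflection
  img <- backproject(ps, wt, g)
  v <- img$values
  relerr <- max(abs(v - v[64:1, 64:1])) / max(abs(v))
  expect_lt(relerr, 0.02)
})

test_that("conjugate PAR images are half a rotation apart", {
  sino <- static_scan()
  g <- test_grid(128)
  w <- select_gating_window(sino$timeline, sino$ecg, 0.3, sino$geometry)
  ps <- ramp_filter(rebin(sino, w))
  p1 <- reconstruct_par(ps, g, "first")
  p2 <- reconstruct_par(ps, g, "last")
  expect_equal(p2$angular_center - p1$angular_center, pi, tolerance = 1e-9)
  expect_equal(p2$center_time - p1$center_time,
               sino$geometry$rotation_time / 2, tolerance = 1e-9)
  expect_equal(2 * p1$angular_halfwidth, sino$geometry$fan_angle_rad,
               tolerance = 0.02)
  # static phantom: band-passed conjugate PARs nearly identical
  b1 <- bandpass(p1$image); b2 <- bandpass(p2$image)
  rel <- sqrt(mean((b1$values - b2$values)^2)) / sqrt(mean(b1$values^2))
  expect_lt(rel, 0.01)
  expect_error(reconstruct_par(ps, g, "first", par_angle = 5), "exceeds")
})

test_that("FBP of the static heart preset matches rasterized truth", {
  sino <- static_scan()
  g <- test_grid(128)
  img <- fbp_reconstruct(sino, 0.4, g)
  truth <- rasterize(snapshot(preset_phantom("static"), img$time), g,
                     supersample = 4)
  expect_gt(mssim(img, truth), 0.95)
  expect_lt(rmse_hu(img, truth), 30)
})
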
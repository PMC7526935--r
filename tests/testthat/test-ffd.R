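make_mvf <- function(g = 12, spacing = 10, origin = c(-55, -55), C = NULL) {
  if (is.null(C)) C <- array(0, c(g, g, 2))
  motion_vector_field(C, spacing, origin)
}

test_that("zero control grid displaces nothing", {
  mvf <- make_mvf()
  pts <- cbind(runif(20, -30, 30), runif(20, -30, 30))
  expect_equal(ffd_displace(mvf, pts), matrix(0, 20, 2))
})

test_that("uniform controls reproduce a pure translation (partition of unity)", {
  C <- array(0, c(12, 12, 2)); C[, , 1] <- 3.2; C[, , 2] <- -1.7
  mvf <- make_mvf(C = C)
  pts <- cbind(seq(-30, 30, length.out = 17), seq(30, -30, length.out = 17))
  d <- ffd_displace(mvf, pts)
  expect_equal(d[, 1], rep(3.2, 17), tolerance = 1e-12)
  expect_equal(d[, 2], rep(-1.7, 17), tolerance = 1e-12)
})

test_that("a single control bump acts locally with tensor-product weights", {
  C <- array(0, c(12, 12, 2)); C[6, 7, 1] <- 1
  mvf <- make_mvf(C = C)
  # at the grid point of control (6,7) (0-based (5,6)): weight = (4/6)*(4/6)
  p_on <- c(-55 + 5 * 10, -55 + 6 * 10)
  expect_equal(ffd_displace(mvf, rbind(p_on))[1, 1], (4 / 6)^2)
  # one spacing away in x: B3(1) * B3(0) = (1/6)*(4/6)
  expect_equal(ffd_displace(mvf, rbind(p_on + c(10, 0)))[1, 1], (1 / 6) * (4 / 6))
  # outside the 4x4 support: zero
  expect_equal(ffd_displace(mvf, rbind(p_on + c(25, 0)))[1, 1], 0)
})

test_that("points outside the extent are clamped with a warning", {
  C <- array(1, c(8, 8, 2))
  mvf <- motion_vector_field(C, 10, c(-35, -35))
  expect_warning(d <- ffd_displace(mvf, rbind(c(500, 0))), "clamped")
  expect_true(all(is.finite(d)))
})

test_that("dense evaluation agrees with pointwise evaluation", {
  set.seed(3)
  C <- array(rnorm(12 * 12 * 2), c(12, 12, 2))
  mvf <- make_mvf(C = C)
  xs <- seq(-30, 30, length.out = 9)
  dd <- ffd_dense(mvf, xs, xs)
  pts <- as.matrix(expand.grid(x = xs, y = xs))
  d <- ffd_displace(mvf, pts)
  expect_equal(as.vector(dd$Dx), d[, 1], tolerance = 1e-12)
  expect_equal(as.vector(dd$Dy), d[, 2], tolerance = 1e-12)
})

test_that("dyadic subdivision preserves the represented field", {
  set.seed(4)
  g <- 14
  C <- array(rnorm(g * g * 2, sd = 3), c(g, g, 2))
  coarse <- motion_vector_field(C, 12, c(-80, -80))
  fineC <- subdivide_controls(C)
  fine <- motion_vector_field(fineC, 6, c(-80, -80))
  xs <- seq(-35, 35, length.out = 11)
  dc <- ffd_dense(coarse, xs, xs)
  df <- ffd_dense(fine, xs, xs)
  expect_equal(df$Dx, dc$Dx, tolerance = 1e-10)
  expect_equal(df$Dy, dc$Dy, tolerance = 1e-10)
})

test_that("temporal scaling is antisymmetric about the target time", {
  C <- array(0, c(10, 10, 2)); C[, , 1] <- 6
  mvf <- motion_vector_field(C, 12, c(-55, -55), t_start = 1, t_end = 1.125)
  pts <- rbind(c(0, 0), c(10, -5))
  mid <- temporal_scale(mvf, 1.0625)
  expect_equal(mid$alpha, 0)
  expect_equal(mid$displace(pts), matrix(0, 2, 2))
  e <- temporal_scale(mvf, 1.125)
  expect_equal(e$alpha, 0.5)
  expect_equal(e$displace(pts)[, 1], c(3, 3))
  s <- temporal_scale(mvf, 1)
  expect_equal(s$alpha, -0.5)
  expect_equal(s$displace(pts)[, 1], c(-3, -3))
  expect_error(temporal_scale(mvf, 2), "outside")
  # predict() applies the same linear model
  expect_equal(predict(mvf, pts, t = 1.125)[, 1], c(3, 3))
})

test_that("registration recovers identity and pure translation", {
  sino <- static_scan()
  g <- test_grid(128)
  w <- select_gating_window(sino$timeline, sino$ecg, 0.3, sino$geometry)
  ps <- ramp_filter(rebin(sino, w))
  img <- bandpass(reconstruct_par(ps, g, "first")$image)
  # identity: moving == fixed
  mvf0 <- register_ffd(img, img, registration_config(maxit = 20))
  dd <- ffd_dense(mvf0, g$centers, g$centers)
  expect_lt(max(sqrt(dd$Dx^2 + dd$Dy^2)), 0.1 * g$pixel_size)
  # translation by one pixel pitch multiple: moving(x) = fixed(x - t) means
  # fixed(x) = moving(x + t), so the recovered field should be +t
  shift_px <- 3
  t_mm <- shift_px * g$pixel_size
  mv <- img
  mv$values <- rbind(img$values[-(1:shift_px), ],
                     img$values[rep(1, shift_px), ])  # shift -x
  # structure at x in fixed appears at x - t in moving: d = -t
  mvf1 <- register_ffd(img, mv, registration_config(maxit = 150))
  dd1 <- ffd_dense(mvf1, g$centers, g$centers)
  gm <- abs(bandpass(img$values)) > 0.2 * max(abs(img$values))
  expect_lt(abs(median(dd1$Dx[gm]) - (-t_mm)), 0.5)
  expect_lt(abs(median(dd1$Dy[gm])), 0.5)
})

test_that("registration objective is non-increasing within and across levels", {
  sino <- static_scan()
  g <- test_grid(128)
  w <- select_gating_window(sino$timeline, sino$ecg, 0.3, sino$geometry)
  ps <- ramp_filter(rebin(sino, w))
  p1 <- reconstruct_par(ps, g, "first")
  p2 <- reconstruct_par(ps, g, "last")
  mvf <- estimate_motion(p1, p2)
  for (lv in mvf$diagnostics$levels)
    expect_lte(lv$objective_final, lv$objective_initial + 1e-12)
})

test_that("evaluated displacements never exceed the cap", {
  set.seed(5)
  sino <- static_scan()
  g <- test_grid(64)
  # huge artificial controls get projected back to the cap
  gd <- ffd_grid_for(g$centers[1], g$centers[g$n], 14.4)
  C <- array(rnorm(gd$g^2 * 2, sd = 30), c(gd$g, gd$g, 2))
  mvf <- motion_vector_field(C, 14.4, c(gd$origin, gd$origin))
  # reuse the projection step applied at the end of register_ffd
  dd <- ffd_dense(mvf, g$centers, g$centers)
  mmax <- sqrt(max(dd$Dx^2 + dd$Dy^2))
  expect_gt(mmax, 14.3)
  mvf$controls <- mvf$controls * (14.3 / mmax)
  dd2 <- ffd_dense(mvf, g$centers, g$centers)
  expect_lte(sqrt(max(dd2$Dx^2 + dd2$Dy^2)), 14.3 + 1e-9)
})
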
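test_that("cardiac phase maps time to R-R fraction", {
  expect_equal(cardiac_phase(ecg_model(60), 0.5), 0.5)
  expect_equal(cardiac_phase(ecg_model(80), 0.75), 0)
  expect_equal(cardiac_phase(ecg_model(100, t0_rpeak = 0.1), 0.4), 0.5)
  expect_error(ecg_model(0), "positive")
  # periodicity and range over many times
  ecg <- ecg_model(73, t0_rpeak = 0.21)
  t <- seq(-3, 7, by = 0.013)
  ph <- cardiac_phase(ecg, t)
  expect_true(all(ph >= 0 & ph < 1))
  expect_equal(cardiac_phase(ecg, t + 60 / 73), ph)
})

test_that("phase_time inverts cardiac_phase within a cycle", {
  ecg <- ecg_model(84, t0_rpeak = 0.4)
  for (p in c(0, 0.3, 0.7, 0.99))
    expect_equal(cardiac_phase(ecg, phase_time(ecg, p, cycle_index = 2)), p)
})

test_that("motion laws are periodic, continuous and amplitude-bounded", {
  ph <- seq(0, 1, by = 1e-3)
  for (kind in c("harmonic", "rest-and-jerk", "triangle")) {
    law <- motion_law(kind, amplitude = 5, phase_of_rest = 0.875,
                      duty = 0.51, phase_of_peak = 0.45, duty_peak = 0.1)
    v <- motion_value(law, ph)
    expect_true(all(abs(v) <= 5 + 1e-12), info = kind)
    expect_equal(motion_value(law, ph + 1), v, info = kind)
    # continuity: no jump anywhere near the size of the amplitude
    expect_lt(max(abs(diff(v))), 0.1)
  }
})

test_that("rest-and-jerk is quiescent throughout its rest window", {
  law <- motion_law("rest-and-jerk", amplitude = 8, phase_of_rest = 0.875,
                    duty = 0.51, phase_of_peak = 0.45, duty_peak = 0.1)
  v_rest <- motion_value(law, 0.875)
  v_edge <- motion_value(law, 0.875 + 0.51 / 2)
  expect_lt(abs(v_edge - v_rest), 8 * 0.05)
  # and moves fast mid-transition
  mid <- motion_value(law, c(0.28, 0.32))
  expect_gt(abs(diff(mid)), 8 * 0.02)
})

test_that("snapshot freezes primitives and respects periodicity", {
  p <- preset_phantom("xcat_like", heart_rate = 75)
  s1 <- snapshot(p, 0.37)
  s2 <- snapshot(p, 0.37 + 60 / 75)
  expect_equal(s1, s2, ignore_attr = TRUE)
  expect_equal(length(s1), length(p$primitives))
  expect_equal(sapply(s1, `[[`, "label"), sapply(p$primitives, `[[`, "label"))
  # static preset frozen at any two times is identical
  ps <- preset_phantom("static")
  expect_equal(snapshot(ps, 0.1), snapshot(ps, 0.9), ignore_attr = TRUE)
})

test_that("snapshot additive decomposition reproduces painted values", {
  p <- preset_phantom("xcat_like", heart_rate = 60)
  fr <- snapshot(p, 0.22)
  # at any sample point, summing mu_add over covering primitives must give
  # the painted (last-covering) mu
  set.seed(7)
  xs <- runif(500, -100, 100); ys <- runif(500, -80, 80)
  painted <- rep(0, 500); additive <- rep(0, 500)
  for (fp in fr) {
    ins <- inside_frozen(fp, xs, ys)
    painted[ins] <- fp$mu
    additive[ins] <- additive[ins] + fp$mu_add
  }
  expect_equal(additive, painted, tolerance = 1e-12)
})

test_that("partially overlapping non-nested primitives are rejected", {
  p <- dynamic_phantom(list(
    tv_primitive("a", "ellipse", 0.02, c(0, 0), c(20, 20)),
    tv_primitive("b", "ellipse", 0.03, c(25, 0), c(10, 10))),
    ecg_model(60), fov_extent = 90)
  expect_error(snapshot(p, 0), "partially overlap")
})

test_that("rasterize paints last-covering primitive and matches disk area", {
  g <- test_grid(128)
  expect_equal(rasterize(list(), g)$values, matrix(0, 128, 128))
  # single centred disk: pixel count at value mu ~ pi r^2 / pixel area
  fr <- snapshot(disk_phantom(r = 30, mu = 0.05, center = c(0, 0)), 0)
  img <- rasterize(fr, g)
  count <- sum(img$values == 0.05)
  expect_equal(count * g$pixel_size^2, pi * 30^2, tolerance = 0.02)
  # annulus interior is zero
  pa <- dynamic_phantom(list(
    tv_primitive("ring", "annulus", 0.03, c(0, 0), c(40, 35),
                 inner_semi_axes = c(25, 20))),
    ecg_model(60), fov_extent = 90)
  ia <- rasterize(snapshot(pa, 0), g)
  expect_equal(sample_image(ia, 0, 0), 0)
  expect_equal(sample_image(ia, 32, 0), 0.03)
})

test_that("phantom presets have the advertised structure", {
  pm <- preset_phantom("mocomo_like")
  expect_equal(length(pm$primitives), 7)   # water + six artery rods
  expect_equal(sum(sapply(pm$primitives, function(x) x$shape == "notched_rod")), 3)
  px <- preset_phantom("xcat_like", artery_d = 3)
  arts <- Filter(function(x) x$label %in% c("RCA", "LAD", "LCX"), px$primitives)
  expect_equal(length(arts), 3)
  for (a in arts) expect_equal(a$semi_axes(0), c(1.5, 1.5))
  expect_error(preset_phantom("nope"), "unknown")
})

test_that("primitive centres never move farther than their declared amplitude", {
  for (preset in c("xcat_like", "mocomo_like", "alpha_like")) {
    p <- preset_phantom(preset, heart_rate = 70)
    ph <- seq(0, 0.995, by = 0.005)   # one period, no duplicated endpoint
    for (prim in p$primitives) {
      if (!is.finite(prim$amplitude)) next
      ctr <- vapply(ph, function(x) prim$center(x), numeric(2))
      mid <- rowMeans(ctr)
      disp <- sqrt(colSums((ctr - mid)^2))
      expect_lte(max(disp), prim$amplitude + 1e-9)
    }
  }
})

test_that("rasterized snapshots are bit-identical one period apart", {
  p <- preset_phantom("alpha_like", heart_rate = 90)
  g <- test_grid(64)
  i1 <- rasterize(snapshot(p, 0.4), g)
  i2 <- rasterize(snapshot(p, 0.4 + 60 / 90), g)
  expect_identical(i1$values, i2$values)
})

test_that("increasing a primitive's mu never decreases covered pixels", {
  g <- test_grid(64)
  base <- disk_phantom(r = 25, mu = 0.03, center = c(10, 5))
  hi <- disk_phantom(r = 25, mu = 0.04, center = c(10, 5))
  d <- rasterize(snapshot(hi, 0), g)$values - rasterize(snapshot(base, 0), g)$values
  expect_true(all(d >= 0))
})
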
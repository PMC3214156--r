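# Closed-form geometry: acceptance angle, tilt correction, spot size,
# solid-angle fraction, overlap fraction, and the two efficiency models.

test_that("acceptance angle matches arcsin(NA/n0)", {
  expect_equal(acceptance_angle(std_fiber(100)), 12.70903, tolerance = 1e-5)
  expect_equal(round(acceptance_angle(std_fiber(100)), 1), 12.7)
  expect_equal(acceptance_angle(fiber_spec(100, 1e-9)), 0, tolerance = 1e-6)
  # in water: verify through the defining relation sin(theta) * n0 = NA
  th <- acceptance_angle(fiber_spec(100, 0.22, 1.33))
  expect_equal(sin(th * pi / 180) * 1.33, 0.22, tolerance = 1e-12)
  expect_equal(th, 9.5213, tolerance = 1e-4)
})

test_that("effective distance reduces to d at normal incidence and grows with tilt", {
  for (d in c(0, 17.3, 500, 2200)) {
    for (size in c(50, 200, 1000)) {
      expect_identical(effective_distance(d, std_fiber(size), tilt = 0), d)
    }
  }
  # hand-evaluated closed form at d = 100, r = 100, NA = 0.22, beta = 15 deg
  expect_equal(effective_distance(100, std_fiber(100), tilt = 15),
               102.062, tolerance = 1e-4)
  expect_equal(effective_distance(0, std_fiber(100), tilt = 0), 0)
  # d' >= d for beta > 0
  f <- std_fiber(200)
  for (b in c(1, 10, 30, 60)) {
    expect_gte(effective_distance(300, f, tilt = b), 300)
  }
  # domain bound: beta >= 90 - theta degenerates
  expect_error(effective_distance(100, f, tilt = 78),
               class = "fiberprobe_domain_error")
})

test_that("spot radius and surface intensity ratio follow the cone geometry", {
  expect_equal(spot_radius(0, std_fiber(200)), 200)
  expect_equal(spot_radius(100, std_fiber(50)), 72.5528, tolerance = 1e-4)
  expect_equal(spot_radius(1200, std_fiber(500)), 770.633, tolerance = 1e-3)
  expect_equal(surface_intensity_ratio(0, std_fiber(100), tilt = 0), 1.0)
  expect_equal(surface_intensity_ratio(0, std_fiber(100), tilt = 60), 0.5,
               tolerance = 1e-12)
  expect_equal(surface_intensity_ratio(200, std_fiber(200)),
               (200 / (200 + 200 * TAN_THETA_022))^2, tolerance = 1e-12)
  expect_equal(surface_intensity_ratio(200, std_fiber(200)), 0.66581,
               tolerance = 1e-4)
  # normal illumination maximizes the surface intensity at fixed distance
  vals <- vapply(c(0, 5, 15, 40), function(b)
    surface_intensity_ratio(150, std_fiber(200), tilt = b), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("solid-angle fraction is 1 at contact and strictly decreasing", {
  f <- std_fiber(200)
  expect_equal(solid_angle_fraction(0, f), 1.0)
  expect_equal(solid_angle_fraction(200, f), 1 - 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(solid_angle_fraction(100, std_fiber(50)), 0.105573,
               tolerance = 1e-5)
  grid <- seq(0, 5000, length.out = 1000)
  om <- solid_angle_fraction(grid, f)
  expect_true(all(om >= 0 & om <= 1))
  expect_true(all(diff(om) < 0))
})

test_that("overlap fraction is zero before onset and continuous at it", {
  f <- std_fiber(100)
  onset <- overlap_onset(f, 10)
  expect_equal(onset, 10 / TAN_THETA_022, tolerance = 1e-12)
  for (dial in c("as_printed", "energy_conserving")) {
    below <- overlap_fraction(seq(0, onset, length.out = 50), f, 10, dial)
    expect_true(all(below == 0))
    just_after <- overlap_fraction(onset * (1 + 1e-8), f, 10, dial)
    expect_lt(just_after, 1e-3)   # continuity at onset
  }
})

test_that("corrected overlap fraction is the exact lens-area fraction", {
  f <- std_fiber(1000)
  # full overlap limit: c/R -> 0 approximated by huge distance
  far <- overlap_fraction(1e9, f, 10, "energy_conserving")
  expect_equal(far, 1.0, tolerance = 1e-5)
  # lens value at r = 1000, r_c = 10, d = 700 agrees with the point-sampling
  # oracle (the independent geometric estimate)
  d_eff <- 700
  ov <- overlap_fraction(d_eff, f, 10, "energy_conserving")
  R <- spot_radius(d_eff, f)
  est <- mc_overlap_fraction(R, 1010, n = 2e5, seed = 42)
  expect_lt(abs(ov - est$estimate), 3 * est$standard_error)
  expect_true(all(overlap_fraction(seq(0, 20000, by = 50), f, 10,
                                   "energy_conserving") <= 1))
})

test_that("as-printed overlap formula inflates and the clamp engages past 1", {
  f <- std_fiber(100)
  grid <- seq(0, 5000, by = 5)
  raw <- overlap_fraction(grid, f, 10, "as_printed", clamp = FALSE)
  clamped <- overlap_fraction(grid, f, 10, "as_printed", clamp = TRUE)
  corrected <- overlap_fraction(grid, f, 10, "energy_conserving")
  # the raw printed formula exceeds 1 in the far field (tends to 2)
  expect_true(any(raw > 1))
  expect_equal(overlap_fraction(1e9, f, 10, "as_printed", clamp = FALSE), 2,
               tolerance = 1e-5)
  # clamp engages exactly where the raw value exceeds 1
  expect_equal(clamped, pmin(pmax(raw, 0), 1))
  # printed >= corrected everywhere in the overlap regime
  expect_true(all(raw >= corrected - 1e-12))
})

test_that("single-fiber efficiency reproduces the printed distance checkpoints", {
  # 50 um curve at d = 100: ~20% of contact (computed 22.2%)
  r50 <- single_fiber_efficiency(single_probe(100), std_fiber(50))
  expect_equal(r50$efficiency_normalized, 0.22229, tolerance = 1e-4)
  # 500 um curve at d = 1200: ~20% of contact (computed 18.3%)
  r500 <- single_fiber_efficiency(single_probe(1200), std_fiber(500))
  expect_equal(r500$efficiency_normalized, 0.182731, tolerance = 1e-4)
  # contact normalizes to exactly 1 in both dialects
  for (dial in c("as_printed", "energy_conserving")) {
    expect_equal(single_fiber_efficiency(single_probe(0, dialect = dial),
                                         std_fiber(200))$efficiency_normalized, 1.0)
  }
})

test_that("single-fiber efficiency is non-increasing in distance (both dialects)", {
  for (dial in c("as_printed", "energy_conserving")) {
    for (size in c(50, 200, 500)) {
      vals <- vapply(seq(0, 5 * size, length.out = 200), function(d)
        single_fiber_efficiency(single_probe(d, dialect = dial),
                                std_fiber(size))$efficiency, numeric(1))
      expect_true(all(diff(vals) <= 1e-12),
                  info = sprintf("%s, size %g", dial, size))
      expect_equal(which.max(vals), 1L)   # argmax at contact
    }
  }
})

test_that("multi-fiber efficiency vanishes below onset and peaks in the interior", {
  f <- std_fiber(1000)
  onset <- overlap_onset(f, 10)
  expect_equal(onset, 44.3409, tolerance = 1e-4)
  for (d in c(0, 10, 44)) {
    expect_equal(multi_fiber_efficiency(multi_probe(d), f)$efficiency, 0)
  }
  e100 <- multi_fiber_efficiency(multi_probe(100), f)$efficiency
  e700 <- multi_fiber_efficiency(multi_probe(700), f)$efficiency
  e2000 <- multi_fiber_efficiency(multi_probe(2000), f)$efficiency
  expect_gt(e700, e100)
  expect_gt(e700, e2000)
  expect_equal(e700, 0.21672, tolerance = 1e-4)
})

test_that("mode mismatches are rejected", {
  expect_error(single_fiber_efficiency(multi_probe(100), std_fiber(100)),
               class = "fiberprobe_invariant_error")
  expect_error(multi_fiber_efficiency(single_probe(100), std_fiber(100)),
               class = "fiberprobe_invariant_error")
})

test_that("tilting a 200-um multi-fiber probe can beat normal incidence", {
  f <- std_fiber(200)
  d <- 60   # just past the normal-incidence onset (44.3 um)
  e0 <- multi_fiber_efficiency(multi_probe(d, tilt = 0), f)$efficiency
  e_tilt <- vapply(c(5, 10, 15), function(b)
    multi_fiber_efficiency(multi_probe(d, tilt = b), f)$efficiency, numeric(1))
  expect_true(any(e_tilt > e0))
})
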
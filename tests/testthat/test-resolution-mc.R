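test_that("simulated trials conserve photons and align bins on the midpoint", {
  scene <- two_point_scene(150e-9, (50e-9)^2, 1e4, 40e-9)
  tr <- simulate_trial(scene, seed = 7)
  expect_identical(sum(tr$counts), 10000L)
  # bin edges are integer multiples of the pixel, so 0 (the midpoint between
  # the true centers) is an edge
  expect_true(any(abs(tr$edges) < 1e-18))
  expect_equal(tr$edges / 40e-9, round(tr$edges / 40e-9), tolerance = 1e-9)
  # reproducible from the seed
  tr2 <- simulate_trial(scene, seed = 7)
  expect_identical(tr, tr2)
  # conservation across scenes
  for (d in c(0, 50e-9, 1000e-9)) {
    sc <- two_point_scene(d, (50e-9)^2, 3000, 25e-9)
    expect_identical(sum(simulate_trial(sc, seed = 1)$counts), 3000L)
  }
})

test_that("contrast criterion behaves at the extremes", {
  s2 <- (50e-9)^2
  # coincident objects: no dip, unresolved
  sc0 <- two_point_scene(0, s2, 1e4, 40e-9)
  a0 <- assess_trial(simulate_trial(sc0, seed = 3), sc0)
  expect_false(a0$resolved)
  expect_equal(a0$contrast, 0)
  # far-separated objects: empty valley, contrast ~ 1
  scf <- two_point_scene(20 * 50e-9, s2, 1e4, 40e-9)
  af <- assess_trial(simulate_trial(scf, seed = 3), scf)
  expect_true(af$resolved)
  expect_gt(af$contrast, 0.999)
  expect_lt(af$contrast, 1 + 1e-12)
  # the Eq identity: equal valley and peak means zero contrast (flat density)
  flat <- density_contrast(function(x) rep(1, length(x)), -1, 1)
  expect_null(flat)
})

test_that("fitted contrast matches the analytic mixture contrast at large N", {
  sigma <- 50e-9
  d <- 2.8 * sigma
  sc <- two_point_scene(d, sigma^2, 1e6, 10e-9)
  ct <- analytic_contrast(d, sigma)
  expect_equal(ct, 0.2653, tolerance = 1e-3)
  a <- assess_trial(simulate_trial(sc, seed = 1), sc)
  expect_equal(a$contrast, ct, tolerance = 0.02)
  expect_true(a$resolved)
})

test_that("well-separated static scenes resolve in >= 95% of trials", {
  # d = 3 sigma with generous photons, matching the simulation shortcut
  frac <- resolved_fraction(3 * 50e-9, (50e-9)^2, 1e4, 40e-9,
                            n_trials = 100, seed = 11)
  expect_gte(frac, 0.95)
})

test_that("resolved fraction grows with the photon count (paired seeds)", {
  s2 <- (50e-9)^2
  fr <- vapply(c(100, 400, 4000), function(N)
    resolved_fraction(125e-9, s2, N, 40e-9, n_trials = 100, seed = 3),
    numeric(1))
  expect_true(all(diff(fr) >= -0.02))   # monotone up to MC noise
  expect_gt(fr[3] - fr[1], 0.1)         # and genuinely increasing
})

test_that("resolution estimate agrees with an exhaustive separation scan", {
  s2 <- (50e-9)^2
  est <- resolution_estimate(s2, 2000, 40e-9, n_trials = 60, seed = 21)
  # brute-force oracle: fine scan of d at the same trial budget
  ds <- seq(80e-9, 200e-9, by = 5e-9)
  fr <- vapply(seq_along(ds), function(i)
    resolved_fraction(ds[i], s2, 2000, 40e-9, n_trials = 60,
                      seed = 100 + i), numeric(1))
  d_scan <- ds[which(fr >= 0.95)[1]]
  # agreement within one geometric grid step (factor 1.25)
  expect_lt(abs(est$resolution - d_scan) / d_scan, 0.25)
  expect_false(est$shortcut_bound)
  # the estimate is bitwise reproducible from its seed
  est2 <- resolution_estimate(s2, 2000, 40e-9, n_trials = 60, seed = 21)
  expect_identical(est, est2)
})

test_that("resolution is non-increasing in photons for a static scene", {
  s2 <- (50e-9)^2
  r_low <- resolution_estimate(s2, 300, 40e-9, n_trials = 60, seed = 5)
  r_high <- resolution_estimate(s2, 10000, 40e-9, n_trials = 60, seed = 5)
  expect_lte(r_high$resolution, r_low$resolution * 1.05)
})

test_that("frozen-medium resolution ignores the acquisition time", {
  s <- fwhm_to_sigma(100e-9)
  slow <- motional_blur_for(100e-9, 1e6, s, medium_state(frozen = TRUE),
                            photophysics(emission_rate = 2e4))
  fast <- motional_blur_for(100e-9, 1e6, s, medium_state(frozen = TRUE))
  expect_identical(slow$blur$sigma_mb2, fast$blur$sigma_mb2)
  expect_identical(
    resolution_estimate(slow$blur$sigma_mb2, 5000, 40e-9, n_trials = 40,
                        seed = 2)$resolution,
    resolution_estimate(fast$blur$sigma_mb2, 5000, 40e-9, n_trials = 40,
                        seed = 2)$resolution)
})

test_that("resolution_curve tabulates deterministic rt/cryo estimates", {
  s <- fwhm_to_sigma(150e-9)
  tab <- resolution_curve(c(50e-9, 200e-9), 2e4, s, n_trials = 40, seed = 9)
  expect_identical(nrow(tab), 4L)
  expect_setequal(unique(tab$state), c("rt", "cryo"))
  # Brownian blur always worsens resolution
  for (sz in unique(tab$size_m)) {
    rt <- tab$resolution_m[tab$size_m == sz & tab$state == "rt"]
    cr <- tab$resolution_m[tab$size_m == sz & tab$state == "cryo"]
    expect_gt(rt, cr)
  }
  tab2 <- resolution_curve(c(50e-9, 200e-9), 2e4, s, n_trials = 40, seed = 9)
  expect_identical(tab, tab2)
})
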
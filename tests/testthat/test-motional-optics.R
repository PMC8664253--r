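test_that("Stokes-Einstein diffusion coefficient matches direct arithmetic", {
  med <- medium_state(temperature = 310.15, viscosity = 6.922e-4)
  D50 <- diffusion_coefficient(med, particle_structure(50e-9))
  expect_equal(D50, kB * 310.15 / (6 * pi * 6.922e-4 * 50e-9))
  expect_equal(D50, 6.56e-12, tolerance = 1e-3)
  # D scales as 1/r
  D5 <- diffusion_coefficient(med, particle_structure(5e-9))
  expect_equal(D5 / D50, 10, tolerance = 1e-12)
  # D * eta invariant at fixed T, r
  for (eta in c(1e-4, 6.922e-4, 5e-3)) {
    Dx <- diffusion_coefficient(medium_state(310.15, eta),
                                particle_structure(50e-9))
    expect_equal(Dx * eta, D50 * 6.922e-4, tolerance = 1e-12)
  }
})

test_that("frozen medium means zero diffusion, any radius", {
  frozen <- medium_state(frozen = TRUE)
  expect_identical(diffusion_coefficient(frozen, particle_structure(50e-9)), 0)
  expect_identical(diffusion_coefficient(frozen, particle_structure(0)), 0)
  expect_error(diffusion_coefficient(medium_state(), particle_structure(0)),
               "radius")
})

test_that("mean square displacement is 4 D dt with zero and error cases", {
  expect_equal(mean_square_displacement(6.56e-12, 0.05), 1.312e-12)
  expect_identical(mean_square_displacement(1e-11, 0), 0)
  expect_identical(mean_square_displacement(0, 123), 0)
  expect_error(mean_square_displacement(-1e-12, 1))
  expect_error(mean_square_displacement(1e-12, -1))
})

test_that("photon budget maps to acquisition time and collected photons", {
  ph <- photophysics(emission_rate = 2e6, collection_efficiency = 0.1)
  expect_equal(acquisition_time(1e5, ph), 0.05)
  expect_identical(acquisition_time(0, ph), 0)
  expect_equal(collected_photons(1e5, ph), 1e4)
  expect_equal(collected_photons(19, ph), 1)   # floor
})

test_that("motional blur variance adds PSF, MSD and structure terms", {
  s <- fwhm_to_sigma(100e-9)
  expect_equal(s, 100e-9 / 2.355)
  b0 <- motional_blur_variance(s, 0, 0)
  expect_equal(b0$sigma_mb2 * 1e18, 1803.09, tolerance = 1e-4)
  b1 <- motional_blur_variance(s, 1.312e-12, 50e-9)
  expect_equal(b1$sigma_mb2, s^2 + 1.312e-12 + 2500e-18)
  bc <- motional_blur_variance(s, 0, 50e-9)
  expect_equal(bc$sigma_mb2 * 1e18, 4303.09, tolerance = 1e-4)
  # point-label structures do not add their size
  expect_equal(motional_blur_variance(s, 0, 50e-9,
                                      uniform_label = FALSE)$sigma_mb2, s^2)
  # additivity of the variance terms on random inputs
  set.seed(42)
  for (i in 1:20) {
    v <- runif(4, 0, 1e-13)
    lhs <- motional_blur_variance(sqrt(v[1]), v[2] + v[3], sqrt(v[4]))$sigma_mb2
    rhs <- motional_blur_variance(sqrt(v[1]), v[2], 0)$sigma_mb2 +
      motional_blur_variance(0, v[3], 0)$sigma_mb2 + v[4]
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("localization variance reproduces the pixelated formula", {
  # background-free: v = (sigma^2 + a^2/12)/N
  v0 <- localization_variance(10000e-18, 100e-9, 1000)
  expect_equal(v0 * 1e18, (10000 + 100^2 / 12) / 1000, tolerance = 1e-12)
  expect_equal(sqrt(v0) * 1e9, 3.2914, tolerance = 1e-4)
  # full two-term formula, independent evaluation
  s2a <- 10000e-18 + (100e-9)^2 / 12
  v1_expected <- s2a / 1000 +
    16 * pi * s2a^2 * 20 / (3 * (100e-9)^2 * 1000^2)
  expect_equal(localization_variance(10000e-18, 100e-9, 1000, 20, 0),
               v1_expected, tolerance = 1e-12)
  expect_equal(v1_expected * 1e18, 14.77, tolerance = 1e-3)
  # small-pixel, background-free limit: v -> sigma^2 / N
  expect_equal(localization_variance(10000e-18, 1e-12, 1000) * 1000,
               10000e-18, tolerance = 1e-6)
  expect_error(localization_variance(1e-14, 0, 1000), "pixel_size")
  # strictly decreasing in N
  vs <- localization_variance(4000e-18, 100e-9, c(100, 300, 1000, 3000, 1e4),
                              bg_mean = 5, bg_var = 2)
  expect_true(all(diff(vs) < 0))
})

test_that("precision improvement chain gives ~16x at 100 nm, ~70x at 10 nm", {
  s <- fwhm_to_sigma(100e-9)
  ir100 <- improvement_ratio(100e-9, 1e5, s)
  ir10 <- improvement_ratio(10e-9, 1e5, s)
  # order-of-magnitude agreement with the printed ~10x / 100-fold claims
  expect_gt(ir100$fold, 5); expect_lt(ir100$fold, 20)
  expect_gt(ir10$fold, 50); expect_lt(ir10$fold, 200)
  expect_gt(ir10$fold, ir100$fold)   # smaller structures gain more
  # identical static media: fold is exactly 1
  same <- improvement_ratio(100e-9, 1e5, s,
                            medium_rt = medium_state(frozen = TRUE))
  expect_equal(same$fold, 1)
  # frozen-medium precision is invariant to the photon-emission time scale
  slow <- improvement_ratio(100e-9, 1e5, s,
                            phot = photophysics(emission_rate = 2e4))
  fast <- improvement_ratio(100e-9, 1e5, s)
  expect_equal(slow$precision_cryo, fast$precision_cryo)
  # cryo quantum-yield factor only enters when asked
  qy <- improvement_ratio(100e-9, 1e5, s, use_cryo_qy = TRUE)
  expect_equal(qy$n_cryo, floor(1e4 * 1.2))
  expect_gt(qy$fold, fast$fold)
})
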
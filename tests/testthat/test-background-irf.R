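test_that("image background on a uniform image is exact", {
  counts <- array(0, c(1, 32, 32, 8))
  counts[1, , , 3] <- 7   # constant 7 photons per pixel, one bin
  st <- tcspc_stack(counts, 1, 12.5)
  bi <- estimate_background_image(st, window = 21)
  expect_identical(bi$per_pixel, 7)
  expect_identical(bi$total, 7 * 32 * 32)
})

test_that("single-pixel hot noise does not disturb the image estimate", {
  counts <- array(0, c(1, 32, 32, 8))
  counts[1, , , 3] <- 7
  counts[1, 10, 10, 3] <- 1000
  st <- tcspc_stack(counts, 1, 12.5)
  bi <- estimate_background_image(st, window = 21)
  # candidate windows containing the hot pixel have a higher mean; the
  # tie-break picks a clean window
  expect_identical(bi$per_pixel, 7)
})

test_that("image background recovers a Poisson rate with structures present", {
  spec <- scene_spec(photons_per_pixel = 2000, background_rate = 5,
                     n_frames = 1, seed = 13)
  gen <- generate_tcspc_stack(spec)
  bi <- estimate_background_image(gen$stack, window = 21)
  se <- sqrt(5 / 21^2)   # SE of a window mean of Poisson(5) pixels
  expect_lt(abs(bi$per_pixel - 5), 3 * se + 0.15)
})

test_that("histogram background recovers a flat per-bin offset", {
  # short lifetime so the decay tail is negligible at the period end
  spec <- scene_spec(width = 16, height = 16, n_frames = 1,
                     photons_per_pixel = 2000, background_rate = 12,
                     lifetimes = c(donor_only = 0.9, active = 0.9,
                                   inactive = 3.5),
                     donor_fraction = 1,
                     blobs = data.frame(cy = 8, cx = 8, radius = 32,
                                        alpha = 0),
                     seed = 14)
  gen <- generate_tcspc_stack(spec)
  bh <- estimate_background_histogram(gen$stack)
  o_bin <- 12 * 256 / 256   # aggregate offset per bin = npx * rate / n_bins
  o_bin <- 16 * 16 * 12 / 256
  se <- sqrt(o_bin / 51)
  expect_lt(abs(bh$per_bin - o_bin), 3 * se + 0.05 * o_bin)
  expect_equal(bh$total, bh$per_bin * 256)
})

test_that("zero-background stacks give a (near) zero estimate", {
  gen <- mono_stack(tau = 0.9, photons = 2000, n_px = 24, noise_free = FALSE,
                    seed = 3)
  bh <- estimate_background_histogram(gen$stack)
  # no offset: the histogram floor is only the decay tail
  expect_lt(bh$total / sum(gen$stack$counts), 0.01)
})

test_that("image and histogram estimates cross-check on the same scene", {
  spec <- scene_spec(photons_per_pixel = 1500, background_rate = 15,
                     n_frames = 1,
                     lifetimes = c(donor_only = 3.71, active = 0.9,
                                   inactive = 1.2),
                     seed = 15)
  gen <- generate_tcspc_stack(spec)
  bg <- estimate_background(gen$stack)
  expect_true(bg$consistent)
  expect_gt(bg$per_pixel, 0)
  # the image estimate is close; the histogram one over-reads by the
  # wrapped decay tail but stays within its factor-2 cross-check band
  expect_lt(abs(bg$image_based / (15 * 64 * 64) - 1), 0.35)
  expect_lt(abs(log(bg$histogram_based / (15 * 64 * 64))), log(2))
})

test_that("a delta IRF is estimated as (almost) no shift and no width", {
  gen <- mono_stack(tau = 3.71, photons = 4000, n_px = 16, seed = 4,
                    noise_free = FALSE)
  irf <- estimate_irf(gen$stack)
  expect_lt(abs(irf$shift), 0.03)
  expect_lt(irf$width, 0.06)
  expect_equal(irf$tau, 3.71, tolerance = 0.05)
})

test_that("a shifted Gaussian IRF is recovered from the harmonics", {
  gen <- mono_stack(tau = 3.71, photons = 4000, n_px = 16, irf_shift = 0.5,
                    irf_width = 0.3, seed = 5, noise_free = FALSE)
  irf <- estimate_irf(gen$stack)
  expect_lt(abs(irf$shift - 0.5) / 0.5, 0.1)
  expect_lt(abs(irf$width - 0.3) / 0.3, 0.25)
})

test_that("IRF correction returns monoexponential pixels to the semicircle", {
  gen <- mono_stack(tau = 2.5, photons = 5000, n_px = 8, irf_shift = 0.6,
                    irf_width = 0.4, seed = 6, noise_free = TRUE)
  # uncorrected phasors sit off the semicircle
  ph_raw <- phasor_transform(gen$stack)
  res_raw <- abs(sqrt((ph_raw$g - 0.5)^2 + ph_raw$s^2) - 0.5)
  expect_gt(median(res_raw, na.rm = TRUE), 5e-3)
  # corrected with the known IRF they return to it
  ph <- phasor_transform(gen$stack, irf = irf_estimate(0.6, 0.4))
  res <- abs(sqrt((ph$g - 0.5)^2 + ph$s^2) - 0.5)
  expect_lt(max(res, na.rm = TRUE), 1e-3)
})

test_that("too few photons fall back to an identity IRF with a warning", {
  counts <- array(0, c(1, 4, 4, 64))
  counts[1, 1, 1, 1] <- 5
  st <- tcspc_stack(counts, 12.5 / 64, 12.5)
  expect_warning(irf <- estimate_irf(st), "few photons")
  expect_identical(irf$shift, 0)
  expect_identical(irf$width, 0)
})
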
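# minimal phasor_image and fit constructors for unit-level checks
phasor_from_points <- function(g, s, photons = 1000, omega = 0.5027) {
  structure(list(g = g, s = s,
                 photons = matrix(photons, nrow(g), ncol(g)),
                 mask = matrix(TRUE, nrow(g), ncol(g)),
                 omega = omega, laser_period = 2 * pi / omega),
            class = "phasor_image")
}

test_that("pixels at a pure component phasor get the full fraction", {
  w <- 0.5027
  p_in <- lifetime_phasor(3.5, w)
  ph <- phasor_from_points(matrix(p_in[, "g"], 3, 3),
                           matrix(p_in[, "s"], 3, 3))
  fit <- fit_three_components(ph, donor_fraction = 0)
  expect_equal(unname(fit$f_active[2, 2]), 0, tolerance = 1e-10)
  expect_equal(unname(fit$f_inactive[2, 2]), 1, tolerance = 1e-10)
  expect_equal(max(fit$residual, na.rm = TRUE), 0, tolerance = 1e-10)
  p_act <- lifetime_phasor(0.9, w)
  ph2 <- phasor_from_points(matrix(p_act[, "g"], 3, 3),
                            matrix(p_act[, "s"], 3, 3))
  fit2 <- fit_three_components(ph2, donor_fraction = 0)
  expect_equal(unname(fit2$f_active[1, 1]), 1, tolerance = 1e-10)
})

test_that("noise-free mixtures are unmixed exactly", {
  w <- 0.5027
  comp <- rbind(lifetime_phasor(3.71, w), lifetime_phasor(0.9, w),
                lifetime_phasor(3.5, w))
  f <- cbind(0.2, seq(0.05, 0.75, length.out = 9), 0)
  f[, 3] <- 1 - f[, 1] - f[, 2]
  obs <- f %*% comp
  ph <- phasor_from_points(matrix(obs[, 1], 3, 3), matrix(obs[, 2], 3, 3))
  fit <- fit_three_components(ph, donor_fraction = 0.2)
  expect_equal(as.vector(fit$f_active), f[, 2], tolerance = 1e-10)
  expect_equal(as.vector(fit$f_inactive), f[, 3], tolerance = 1e-10)
  # fractions always sum to one
  tot <- fit$f_donor_only + fit$f_active + fit$f_inactive
  expect_equal(as.vector(tot), rep(1, 9), tolerance = 1e-12)
})

test_that("infeasible phasors are projected onto the fraction simplex", {
  w <- 0.5027
  # a point beyond the active vertex cannot be written with f in [0, 0.8]
  p_act <- lifetime_phasor(0.4, w)
  ph <- phasor_from_points(matrix(p_act[, "g"], 2, 2),
                           matrix(p_act[, "s"], 2, 2))
  expect_warning(fit <- fit_three_components(ph, donor_fraction = 0.2),
                 "feasible")
  expect_equal(unname(fit$f_active[1, 1]), 0.8, tolerance = 1e-10)
  expect_true(all(fit$clamped[fit$mask]))
  expect_gt(fit$residual[1, 1], 0)
})

test_that("molecular fractions divide photon fractions by brightness", {
  # two-state reduction: f = (0.5, 0.5) over tau = (1, 3) -> m = (0.75, 0.25)
  fake <- structure(list(
    lifetimes = c(donor_only = 2, active = 1, inactive = 3),
    donor_fraction = 0,
    f_donor_only = matrix(0, 1, 2), f_active = matrix(0.5, 1, 2),
    f_inactive = matrix(0.5, 1, 2),
    residual = matrix(0, 1, 2), clamped = matrix(FALSE, 1, 2),
    photons = matrix(1, 1, 2), mask = matrix(TRUE, 1, 2), omega = 0.5,
    lifetimes_fitted = FALSE), class = "three_component_fit")
  mf <- molecular_fraction_maps(fake)
  expect_equal(unname(mf$m_active[1, 1]), 0.75)
  expect_equal(unname(mf$m_inactive[1, 1]), 0.25)
  expect_equal(unname(mf$alpha[1, 1]), 0.75)
  # equal lifetimes: molecular fractions equal photon fractions
  fake$lifetimes <- c(donor_only = 2, active = 2, inactive = 2)
  mf2 <- molecular_fraction_maps(fake)
  expect_equal(mf2$m_active, fake$f_active)
  # no active photons anywhere: alpha identically zero
  fake$lifetimes <- c(donor_only = 3.71, active = 0.9, inactive = 3.5)
  fake$f_active[] <- 0
  fake$f_inactive[] <- 0.8
  fake$f_donor_only[] <- 0.2
  mf3 <- molecular_fraction_maps(fake)
  expect_equal(as.vector(mf3$alpha), c(0, 0))
})

test_that("molecular -> photon conversion inverts the forward map", {
  lt <- c(donor_only = 3.71, active = 0.9, inactive = 3.5)
  set.seed(20)
  for (i in 1:25) {
    m <- runif(3); m <- m / sum(m)
    f <- photon_fractions_from_molecular(m[1], m[2], m[3], lt)
    # forward: photon -> molecular
    q <- c(f$f_donor_only / lt[1], f$f_active / lt[2], f$f_inactive / lt[3])
    expect_equal(unname(q / sum(q)), m, tolerance = 1e-12)
  }
})

test_that("global lifetime optimization recovers the simulated lifetimes", {
  w <- 0.5027
  comp <- rbind(lifetime_phasor(3.71, w), lifetime_phasor(0.9, w),
                lifetime_phasor(3.5, w))
  set.seed(21)
  n <- 12
  f_act <- runif(n * n, 0.05, 0.7)
  f <- cbind(0.2, f_act, 0.8 - f_act)
  obs <- f %*% comp + matrix(rnorm(2 * n * n, 0, 0.004), ncol = 2)
  ph <- phasor_from_points(matrix(obs[, 1], n, n), matrix(obs[, 2], n, n))
  fit <- fit_three_components(ph, tau_active = 1.4, tau_inactive = 3.0,
                              donor_fraction = 0.2, fit_lifetimes = TRUE)
  expect_equal(unname(fit$lifetimes["active"]), 0.9, tolerance = 0.15)
  expect_equal(unname(fit$lifetimes["inactive"]), 3.5, tolerance = 0.25)
})

test_that("summary and coef expose the fitted state", {
  w <- 0.5027
  p <- lifetime_phasor(3.5, w)
  ph <- phasor_from_points(matrix(p[, "g"], 3, 3), matrix(p[, "s"], 3, 3))
  fit <- fit_three_components(ph, donor_fraction = 0)
  expect_equal(unname(coef(fit)),
               unname(c(donor_only = 3.71, active = 0.9, inactive = 3.5)))
  sm <- summary(fit)
  expect_equal(sm$n_pixels, 9L)
  expect_equal(sm$mean_f_active, 0, tolerance = 1e-10)
})
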
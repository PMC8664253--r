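# Boltzmann constant (J/K), 2019 SI exact value
.kB <- 1.380649e-23

#' Medium state for diffusion calculations
#'
#' Bundles the thermodynamic state of the imaging medium. A frozen medium
#' (vitrified sample under cryo-arrest) is treated as having zero diffusion
#' regardless of the nominal viscosity, since the viscosity of water increases
#' by more than 15 orders of magnitude between 37 degrees C and -196 degrees C.
#'
#' @param temperature Absolute temperature (K). Default 310.15 K (37 degrees C).
#' @param viscosity Dynamic viscosity (Pa s). Default 6.922e-4 Pa s, the
#'   viscosity of water at 37 degrees C.
#' @param frozen Logical; if `TRUE` diffusion is treated as exactly zero.
#' @return An object of class `medium_state`.
#' @seealso [diffusion_coefficient()]
#' @export
medium_state <- function(temperature = 310.15, viscosity = 6.922e-4,
                         frozen = FALSE) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.numeric(viscosity), length(viscosity) == 1L,
            is.logical(frozen), length(frozen) == 1L)
  if (temperature <= 0) stop("'temperature' must be positive (K)")
  if (viscosity <= 0) stop("'viscosity' must be positive (Pa s)")
  structure(list(temperature = temperature, viscosity = viscosity,
                 frozen = frozen), class = "medium_state")
}

#' Fluorescently labeled particle / structure
#'
#' @param radius Hydrodynamic radius (m), also taken as the SD of the Gaussian
#'   image of the structure when uniformly labeled.
#' @param uniform_label Logical; if `TRUE` (default) the structure is uniformly
#'   labeled with many fluorophores, so its finite size contributes `radius^2`
#'   to the effective image variance.
#' @return An object of class `particle_structure`.
#' @export
particle_structure <- function(radius, uniform_label = TRUE) {
  stopifnot(is.numeric(radius), length(radius) == 1L)
  if (radius < 0) stop("'radius' must be >= 0")
  structure(list(radius = radius, uniform_label = isTRUE(uniform_label)),
            class = "particle_structure")
}

#' Fluorophore photophysics
#'
#' @param emission_rate Photons emitted per second while the fluorophore is
#'   active (s^-1). Default 2e6 (2 per microsecond), a rate that avoids
#'   re-excitation and minimizes bleaching.
#' @param collection_efficiency Fraction of emitted photons that reach the
#'   detector, in (0, 1]. Default 0.1.
#' @param cryo_qy_factor Quantum-yield ratio cryo / room temperature
#'   (>= 1). Default 1.2.
#' @return An object of class `photophysics`.
#' @export
photophysics <- function(emission_rate = 2e6, collection_efficiency = 0.1,
                         cryo_qy_factor = 1.2) {
  stopifnot(is.numeric(emission_rate), is.numeric(collection_efficiency),
            is.numeric(cryo_qy_factor))
  if (emission_rate <= 0) stop("'emission_rate' must be positive")
  if (collection_efficiency <= 0 || collection_efficiency > 1)
    stop("'collection_efficiency' must be in (0, 1]")
  if (cryo_qy_factor < 1) stop("'cryo_qy_factor' must be >= 1")
  structure(list(emission_rate = emission_rate,
                 collection_efficiency = collection_efficiency,
                 cryo_qy_factor = cryo_qy_factor), class = "photophysics")
}

#' Convert between FWHM and Gaussian standard deviation
#'
#' The point spread function is described by its full width at half maximum;
#' for a Gaussian, FWHM = 2.355 sigma.
#'
#' @param fwhm,sigma Width (any length unit).
#' @return The corresponding sigma (resp. FWHM) in the same unit.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / 2.355

#' @rdname fwhm_to_sigma
#' @export
sigma_to_fwhm <- function(sigma) sigma * 2.355

#' Stokes-Einstein diffusion coefficient
#'
#' D = k_B T / (6 pi eta r) for a sphere of hydrodynamic radius r in a medium
#' of viscosity eta at absolute temperature T. A frozen medium returns exactly
#' zero: under cryo-arrest objects are static.
#'
#' @param medium A [medium_state()].
#' @param particle A [particle_structure()] (or a bare radius in m).
#' @return Diffusion coefficient (m^2/s).
#' @examples
#' diffusion_coefficient(medium_state(), particle_structure(50e-9))
#' @export
diffusion_coefficient <- function(medium, particle) {
  stopifnot(inherits(medium, "medium_state"))
  r <- if (inherits(particle, "particle_structure")) particle$radius
       else as.numeric(particle)
  if (medium$frozen) return(0)
  if (r <= 0) stop("particle radius must be positive in a non-frozen medium")
  .kB * medium$temperature / (6 * pi * medium$viscosity * r)
}

#' Mean square displacement of 2D Brownian motion
#'
#' MSD = 4 D dt.
#'
#' @param D Diffusion coefficient (m^2/s), >= 0.
#' @param dt Elapsed time (s), >= 0.
#' @return MSD (m^2).
#' @export
mean_square_displacement <- function(D, dt) {
  if (any(D < 0)) stop("'D' must be >= 0")
  if (any(dt < 0)) stop("'dt' must be >= 0")
  4 * D * dt
}

#' Acquisition time and collected photons for a photon budget
#'
#' The time to emit `n_emitted` photons at the configured emission rate, and
#' the number of photons actually collected given the detection efficiency
#' (rounded down).
#'
#' @param n_emitted Number of emitted photons (>= 0).
#' @param phot A [photophysics()].
#' @return `acquisition_time`: time (s). `collected_photons`: photon count.
#' @export
acquisition_time <- function(n_emitted, phot = photophysics()) {
  stopifnot(inherits(phot, "photophysics"))
  if (any(n_emitted < 0)) stop("'n_emitted' must be >= 0")
  n_emitted / phot$emission_rate
}

#' @rdname acquisition_time
#' @export
collected_photons <- function(n_emitted, phot = photophysics()) {
  stopifnot(inherits(phot, "photophysics"))
  if (any(n_emitted < 0)) stop("'n_emitted' must be >= 0")
  floor(n_emitted * phot$collection_efficiency)
}

#' Effective image variance under motional blur
#'
#' The image of a moving, uniformly labeled structure is the convolution of
#' the PSF, the Gaussian displacement distribution accumulated by Brownian
#' motion, and the Gaussian image of the structure itself; the variances add:
#' sigma_MB^2 = sigma_PSF^2 + MSD + r^2.
#'
#' @param sigma_psf SD of the Gaussian PSF (m).
#' @param msd Mean square displacement accumulated during the acquisition
#'   (m^2).
#' @param radius Structure radius (m); included only when `uniform_label`.
#' @param uniform_label Logical, default `TRUE`.
#' @return An object of class `blur_model` with fields `sigma_psf`, `msd`,
#'   `radius` and `sigma_mb2`.
#' @export
motional_blur_variance <- function(sigma_psf, msd = 0, radius = 0,
                                   uniform_label = TRUE) {
  stopifnot(sigma_psf >= 0, msd >= 0, radius >= 0)
  r_eff <- if (isTRUE(uniform_label)) radius else 0
  structure(list(sigma_psf = sigma_psf, msd = msd, radius = r_eff,
                 sigma_mb2 = sigma_psf^2 + msd + r_eff^2),
            class = "blur_model")
}

#' @export
print.blur_model <- function(x, ...) {
  cat("Motional-blur model\n")
  cat(sprintf("  sigma_PSF : %.4g nm\n", x$sigma_psf * 1e9))
  cat(sprintf("  MSD       : %.4g nm^2\n", x$msd * 1e18))
  cat(sprintf("  radius    : %.4g nm\n", x$radius * 1e9))
  cat(sprintf("  sigma_MB^2: %.4g nm^2 (sigma_MB = %.4g nm)\n",
              x$sigma_mb2 * 1e18, sqrt(x$sigma_mb2) * 1e9))
  invisible(x)
}

#' Variance of the estimated position of a single emitter
#'
#' Pixelated maximum-likelihood localization variance
#' \deqn{v = \frac{\sigma^2 + a^2/12}{N} +
#'       \frac{16\pi(\sigma^2 + a^2/12)^2 (b_m + b_v^2)}{3 a^2 N^2}}
#' with sigma^2 the effective image variance (the PSF variance, or the
#' motional-blur variance sigma_MB^2 for a moving structure), a the pixel
#' size, N the collected photons, and b_m, b_v the mean and variance of the
#' background photons per pixel. Localization precision is sqrt(v).
#'
#' @param blur A `blur_model` (from [motional_blur_variance()]) or a bare
#'   effective variance sigma^2 (m^2).
#' @param pixel_size Detector pixel edge in sample space (m), > 0.
#' @param n_photons Collected photons (>= 1).
#' @param bg_mean,bg_var Mean and variance of background photons per pixel.
#' @return Position variance (m^2); `localization_precision` returns its
#'   square root (m).
#' @export
localization_variance <- function(blur, pixel_size, n_photons,
                                  bg_mean = 0, bg_var = 0) {
  s2 <- if (inherits(blur, "blur_model")) blur$sigma_mb2 else as.numeric(blur)
  if (any(pixel_size <= 0))
    stop("'pixel_size' must be positive (background term diverges at 0)")
  if (any(n_photons < 1)) stop("'n_photons' must be >= 1")
  if (any(bg_mean < 0) || any(bg_var < 0)) stop("background terms must be >= 0")
  s2a <- s2 + pixel_size^2 / 12
  s2a / n_photons +
    16 * pi * s2a^2 * (bg_mean + bg_var^2) / (3 * pixel_size^2 * n_photons^2)
}

#' @rdname localization_variance
#' @export
localization_precision <- function(blur, pixel_size, n_photons,
                                   bg_mean = 0, bg_var = 0) {
  sqrt(localization_variance(blur, pixel_size, n_photons, bg_mean, bg_var))
}

#' Motional-blur model for a structure and photon budget in a given medium
#'
#' Convenience chain used throughout: the acquisition time follows from the
#' emitted-photon budget and emission rate, Brownian diffusion over that time
#' sets the MSD (zero for a frozen medium), and the effective variance adds
#' PSF, MSD and structure-size terms.
#'
#' @param structure_diameter Diameter of the uniformly labeled structure (m).
#' @param n_emitted Emitted-photon budget.
#' @param sigma_psf SD of the Gaussian PSF (m).
#' @param medium A [medium_state()].
#' @param phot A [photophysics()].
#' @param uniform_label Passed to [motional_blur_variance()].
#' @return A list with the `blur_model`, the diffusion coefficient `D`,
#'   acquisition time `dt` and collected photons `n_collected`.
#' @export
motional_blur_for <- function(structure_diameter, n_emitted, sigma_psf,
                              medium, phot = photophysics(),
                              uniform_label = TRUE) {
  r <- structure_diameter / 2
  part <- particle_structure(r, uniform_label)
  D <- diffusion_coefficient(medium, part)
  dt <- acquisition_time(n_emitted, phot)
  msd <- mean_square_displacement(D, dt)
  list(blur = motional_blur_variance(sigma_psf, msd, r, uniform_label),
       D = D, dt = dt, n_collected = collected_photons(n_emitted, phot))
}

#' Fold-improvement in localization precision by cryo-arrest
#'
#' Evaluates the full chain (diffusion -> MSD -> effective blur -> pixelated
#' localization variance) once for the room-temperature medium and once for
#' the frozen medium, and returns the ratio of localization precisions
#' (rt / cryo; > 1 means cryo-arrest is better).
#'
#' @inheritParams motional_blur_for
#' @param medium_rt Room-temperature [medium_state()] (`frozen = FALSE`).
#' @param medium_cryo Cryo-arrest [medium_state()] (`frozen = TRUE`).
#' @param pixel_size,bg_mean,bg_var Passed to [localization_variance()].
#' @param use_cryo_qy If `TRUE`, the cryo branch multiplies the collected
#'   photons by the quantum-yield factor `phot$cryo_qy_factor`. Default
#'   `FALSE`, so the two states are compared at equal emitted photons.
#' @return A list of class `improvement_ratio` with precisions (m) and `fold`.
#' @export
improvement_ratio <- function(structure_diameter, n_emitted, sigma_psf,
                              medium_rt = medium_state(),
                              medium_cryo = medium_state(frozen = TRUE),
                              phot = photophysics(),
                              pixel_size = 100e-9, bg_mean = 0, bg_var = 0,
                              use_cryo_qy = FALSE) {
  stopifnot(!medium_rt$frozen || medium_rt$viscosity > 0)
  rt <- motional_blur_for(structure_diameter, n_emitted, sigma_psf, medium_rt,
                          phot)
  cr <- motional_blur_for(structure_diameter, n_emitted, sigma_psf,
                          medium_cryo, phot)
  n_rt <- rt$n_collected
  n_cr <- if (isTRUE(use_cryo_qy)) floor(n_rt * phot$cryo_qy_factor) else n_rt
  p_rt <- localization_precision(rt$blur, pixel_size, n_rt, bg_mean, bg_var)
  p_cr <- localization_precision(cr$blur, pixel_size, n_cr, bg_mean, bg_var)
  structure(list(precision_rt = p_rt, precision_cryo = p_cr,
                 fold = p_rt / p_cr, blur_rt = rt$blur, blur_cryo = cr$blur,
                 n_rt = n_rt, n_cryo = n_cr),
            class = "improvement_ratio")
}

#' @export
print.improvement_ratio <- function(x, ...) {
  cat("Localization-precision improvement by cryo-arrest\n")
  cat(sprintf("  rt  : %.3g nm (N = %d)\n", x$precision_rt * 1e9, x$n_rt))
  cat(sprintf("  cryo: %.3g nm (N = %d)\n", x$precision_cryo * 1e9, x$n_cryo))
  cat(sprintf("  fold: %.3g\n", x$fold))
  invisible(x)
}
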
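#' Scene specification for synthetic TCSPC stacks
#'
#' Describes a field of view populated by circular structures ("blobs",
#' standing in for vesicles and membrane patches) expressing a three-state
#' FRET biosensor, plus uniform background counts, a Gaussian IRF and rigid
#' frame-to-frame drift. The three emitting states are donor-only sensor
#' (unquenched), sensor in the active (high-FRET, short-lifetime)
#' conformation, and sensor in the inactive conformation; the per-blob
#' molecular active fraction alpha and the fixed donor-only photon fraction
#' determine the photon fractions via brightness (lifetime) weighting.
#'
#' @param width,height Image size (px).
#' @param n_frames Number of frames.
#' @param n_bins Microtime bins per laser period. Default 256.
#' @param laser_period Laser repetition period (ns). Default 12.5 (80 MHz).
#' @param photons_per_pixel Expected signal photons per lit pixel over the
#'   whole stack.
#' @param photons_outside Expected signal photons per pixel outside blobs
#'   (default 0, so corners are empty apart from background).
#' @param background_rate Expected background counts per pixel per frame,
#'   spread uniformly over the microtime bins.
#' @param lifetimes Named vector (ns): `donor_only`, `active`, `inactive`.
#'   Defaults 3.71 / 0.9 / 3.5.
#' @param donor_fraction Photon fraction of donor-only sensor (default 0.2).
#' @param blobs Data frame with columns `cy`, `cx`, `radius` (px) and
#'   `alpha` (molecular active fraction in `[0, 1]`).
#' @param alpha_outside Alpha assigned to lit pixels outside any blob (used
#'   only when `photons_outside > 0`).
#' @param irf_shift,irf_width Gaussian IRF delay and SD (ns).
#' @param drift Per-frame drift: either a matrix (n_frames x 2, (dy, dx),
#'   possibly fractional; rounded when applied to the pixel raster) or a
#'   specification list `list(mode = "none"|"linear"|"walk", step = ...)`.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width = 64L, height = 64L, n_frames = 2L,
                       n_bins = 256L, laser_period = 12.5,
                       photons_per_pixel = 1000, photons_outside = 0,
                       background_rate = 0,
                       lifetimes = c(donor_only = 3.71, active = 0.9,
                                     inactive = 3.5),
                       donor_fraction = 0.2,
                       blobs = data.frame(cy = c(18, 36), cx = c(18, 36),
                                          radius = c(12, 12),
                                          alpha = c(0.2, 0.7)),
                       alpha_outside = 0,
                       irf_shift = 0, irf_width = 0,
                       drift = list(mode = "none"), seed = 1L) {
  stopifnot(width >= 1, height >= 1, n_frames >= 1, n_bins >= 2,
            laser_period > 0, photons_per_pixel >= 0, photons_outside >= 0,
            background_rate >= 0, donor_fraction >= 0, donor_fraction <= 1,
            all(lifetimes > 0),
            all(c("donor_only", "active", "inactive") %in% names(lifetimes)),
            all(blobs$alpha >= 0), all(blobs$alpha <= 1),
            alpha_outside >= 0, alpha_outside <= 1, irf_width >= 0)
  structure(as.list(environment()), class = "scene_spec")
}

#' Named scene presets
#'
#' `"lifea2-cryo"`: the cryo-arrest biosensor scene (donor-only 3.71 ns,
#' active 0.9 ns, inactive 3.5 ns, donor-only photon fraction 0.2).
#' `"lifea2-rt"`: the room-temperature counterpart with the shorter
#' unquenched donor lifetime (3.04 ns); the conformational lifetimes are kept
#' nominal since they are not separable at room temperature.
#'
#' @param name Preset name.
#' @param ... Overrides passed to [scene_spec()].
#' @return A [scene_spec()].
#' @export
scene_preset <- function(name = c("lifea2-cryo", "lifea2-rt"), ...) {
  name <- match.arg(name)
  args <- list(...)
  if (name == "lifea2-rt")
    args$lifetimes <- c(donor_only = 3.04, active = 0.9, inactive = 3.5)
  do.call(scene_spec, args)
}

#' Per-frame true drift series
#'
#' @param n_frames Number of frames (>= 1). Frame 1 is always (0, 0).
#' @param mode `"none"`, `"linear"` (constant step per frame) or `"walk"`
#'   (cumulative Gaussian random walk).
#' @param step For `"linear"`: a length-2 (dy, dx) step per frame (a scalar
#'   is used for dy with dx = 0). For `"walk"`: the SD of each increment.
#' @param seed Optional seed (used by `"walk"`).
#' @return Matrix n_frames x 2 of cumulative shifts (dy, dx), in pixels.
#' @export
generate_drift_series <- function(n_frames, mode = c("none", "linear", "walk"),
                                  step = 0.5, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_frames >= 1)
  if (!is.null(seed)) set.seed(seed)
  d <- matrix(0, n_frames, 2L, dimnames = list(NULL, c("dy", "dx")))
  if (n_frames == 1L || mode == "none") return(d)
  if (mode == "linear") {
    st <- if (length(step) == 1L) c(step, 0) else step[1:2]
    d[, 1L] <- (seq_len(n_frames) - 1L) * st[1L]
    d[, 2L] <- (seq_len(n_frames) - 1L) * st[2L]
  } else {
    inc <- matrix(stats::rnorm(2L * (n_frames - 1L), 0, step), ncol = 2L)
    d[-1L, ] <- apply(inc, 2L, cumsum)
  }
  d
}

# photon fractions implied by a molecular active fraction alpha and a fixed
# donor-only photon fraction, using brightness (= lifetime) weighting of the
# sensing states
alpha_to_photon_fractions <- function(alpha, donor_fraction, lifetimes) {
  ta <- lifetimes[["active"]]; ti <- lifetimes[["inactive"]]
  wa <- alpha * ta
  wi <- (1 - alpha) * ti
  f_act <- if (donor_fraction >= 1) rep(0, length(alpha))
           else (1 - donor_fraction) * wa / (wa + wi)
  list(f_donor_only = rep(donor_fraction, length(alpha)),
       f_active = f_act,
       f_inactive = 1 - donor_fraction - f_act)
}

# discrete wrapped Gaussian IRF kernel on the bin grid (offset bins)
irf_kernel <- function(shift, width, n_bins, bin_width) {
  P <- n_bins * bin_width
  if (width <= 0 && shift == 0) {
    k <- numeric(n_bins); k[1L] <- 1
    return(k)
  }
  off <- (seq_len(n_bins) - 1L) * bin_width
  k <- numeric(n_bins)
  sd_eff <- max(width, bin_width / 10)
  for (m in -1:1) k <- k + stats::dnorm(off + m * P, shift, sd_eff)
  k / sum(k)
}

circular_convolve <- function(p, k) {
  n <- length(p)
  Re(stats::fft(stats::fft(p) * stats::fft(k), inverse = TRUE)) / n
}

# rasterize the alpha and intensity maps of a scene at a given (dy, dx)
# offset of the blob centers
rasterize_scene <- function(spec, offset = c(0, 0)) {
  ys <- seq_len(spec$height); xs <- seq_len(spec$width)
  alpha <- matrix(spec$alpha_outside, spec$height, spec$width)
  lit <- matrix(spec$photons_outside > 0, spec$height, spec$width)
  intensity <- matrix(spec$photons_outside, spec$height, spec$width)
  if (nrow(spec$blobs) > 0) for (b in seq_len(nrow(spec$blobs))) {
    cy <- spec$blobs$cy[b] + offset[1L]
    cx <- spec$blobs$cx[b] + offset[2L]
    d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
    inside <- d2 <= spec$blobs$radius[b]^2
    alpha[inside] <- spec$blobs$alpha[b]
    intensity[inside] <- spec$photons_per_pixel
    lit[inside] <- TRUE
  }
  list(alpha = alpha, intensity = intensity, lit = lit)
}

#' Generate a synthetic TCSPC stack with ground truth
#'
#' Per pixel, the expected decay is the photon-fraction-weighted mixture of
#' the three area-normalized wrapped monoexponential components, circularly
#' convolved with the Gaussian IRF kernel, plus a flat background floor.
#' Counts are drawn independently per frame and bin from Poisson
#' distributions (or returned as expectations in noise-free mode). Frames
#' are emitted independently after drifting the blob centers by the
#' per-frame drift.
#'
#' @param spec A [scene_spec()].
#' @param noise_free If `TRUE`, the stack holds expected counts instead of
#'   Poisson draws (useful for machine-precision pipeline checks).
#' @return A list of class `synthetic_flim`: `stack` (a [tcspc_stack()]),
#'   and `truth` with the frame-1 `alpha` map, photon-fraction maps,
#'   `intensity` (expected signal photons per pixel), `lit` mask, `drift`
#'   (true per-frame shifts), and the `spec`.
#' @export
generate_tcspc_stack <- function(spec, noise_free = FALSE) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  drift <- if (is.matrix(spec$drift)) {
    stopifnot(nrow(spec$drift) == spec$n_frames)
    spec$drift
  } else {
    do.call(generate_drift_series,
            c(list(n_frames = spec$n_frames), spec$drift))
  }

  B <- spec$n_bins
  bw <- spec$laser_period / B
  kern <- irf_kernel(spec$irf_shift, spec$irf_width, B, bw)
  pmf_for <- function(alpha) {
    f <- alpha_to_photon_fractions(alpha, spec$donor_fraction, spec$lifetimes)
    p <- f$f_donor_only * discrete_exp_pmf(spec$lifetimes[["donor_only"]], B, bw) +
      f$f_active * discrete_exp_pmf(spec$lifetimes[["active"]], B, bw) +
      f$f_inactive * discrete_exp_pmf(spec$lifetimes[["inactive"]], B, bw)
    pmax(circular_convolve(p, kern), 0)
  }

  counts <- array(0, c(spec$n_frames, spec$height, spec$width, B))
  bg_bin <- spec$background_rate / B
  truth_r <- rasterize_scene(spec, c(0, 0))
  pmf_cache <- new.env(parent = emptyenv())
  for (f in seq_len(spec$n_frames)) {
    sc <- rasterize_scene(spec, drift[f, ])
    avals <- unique(sc$alpha[sc$lit])
    exp_f <- array(bg_bin, c(spec$height, spec$width, B))
    for (av in avals) {
      key <- format(av, digits = 15)
      if (is.null(pmf_cache[[key]])) pmf_cache[[key]] <- pmf_for(av)
      p <- pmf_cache[[key]]
      sel <- sc$lit & sc$alpha == av
      inten <- sc$intensity[sel] / spec$n_frames
      idx <- which(sel)
      for (b in seq_len(B))
        exp_f[idx + (b - 1L) * spec$height * spec$width] <-
          exp_f[idx + (b - 1L) * spec$height * spec$width] + inten * p[b]
    }
    counts[f, , , ] <- if (noise_free) exp_f
                       else array(stats::rpois(length(exp_f), exp_f),
                                  dim(exp_f))
  }

  fr <- alpha_to_photon_fractions(as.vector(truth_r$alpha),
                                  spec$donor_fraction, spec$lifetimes)
  shp <- c(spec$height, spec$width)
  structure(list(
    stack = tcspc_stack(counts, bw, spec$laser_period),
    truth = list(alpha = truth_r$alpha,
                 f_donor_only = matrix(fr$f_donor_only, shp[1L], shp[2L]),
                 f_active = matrix(fr$f_active, shp[1L], shp[2L]),
                 f_inactive = matrix(fr$f_inactive, shp[1L], shp[2L]),
                 intensity = truth_r$intensity, lit = truth_r$lit,
                 drift = drift, spec = spec)),
    class = "synthetic_flim")
}

#' @export
print.synthetic_flim <- function(x, ...) {
  cat("Synthetic FLIM dataset\n")
  print(x$stack)
  cat(sprintf("  lit pixels: %d; alpha levels: %s\n", sum(x$truth$lit),
              paste(sort(unique(x$truth$alpha[x$truth$lit])), collapse = ", ")))
  invisible(x)
}
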
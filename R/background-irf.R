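# 2-D median prefilter. EBImage's constant-time median filter operates on
# intensities normalized to [0, 1]; it is used only to locate the image
# minimum robustly, the background value itself is always a mean over the
# raw image.
median_filter2 <- function(mat, size = 9L) {
  rng <- range(mat)
  if (diff(rng) == 0) return(mat)
  radius <- max(1L, as.integer(floor(size / 2)))
  norm <- (mat - rng[1L]) / diff(rng)
  f <- EBImage::medianFilter(norm, radius)
  f * diff(rng) + rng[1L]
}

# clamp a window of half-width h centered at ctr into [1, n]
window_range <- function(ctr, h, n) {
  lo <- ctr - h; hi <- ctr + h
  if (lo < 1L) { hi <- min(n, hi + (1L - lo)); lo <- 1L }
  if (hi > n) { lo <- max(1L, lo - (hi - n)); hi <- n }
  lo:hi
}

#' Image-based background estimate
#'
#' The frames of the stack are summed into a photon-counting image; after a
#' square median prefilter the position of the minimum is found, and the
#' background is the mean of the *raw* image in a square window centered
#' there. The estimate is the expected background photons per pixel over the
#' whole stack duration.
#'
#' @param stack A [tcspc_stack()].
#' @param window Window edge length in pixels, customarily between 21 and 51
#'   depending on image size. Default 21. Shrunk (with a warning) when larger
#'   than the image.
#' @param median_size Edge of the square median prefilter (default 9).
#' @param margin Border width (px) excluded from the minimum search; the
#'   median prefilter is unreliable within its half-window of the border, and
#'   registration zero-fills frame borders. Default half the median window;
#'   pass the maximum applied registration shift plus that for registered
#'   stacks.
#' @return A list with `per_pixel` (background counts per pixel), `total`
#'   (per-image total), and the minimum `position` used.
#' @export
estimate_background_image <- function(stack, window = 21L, median_size = 9L,
                                      margin = NULL) {
  stopifnot(inherits(stack, "tcspc_stack"))
  img <- intensity_image(stack)
  d <- dim(img)
  if (window > min(d)) {
    warning("background window exceeds the image; shrunk to fit")
    window <- min(d)
  }
  if (is.null(margin)) margin <- median_size %/% 2L
  margin <- min(margin, (min(d) - 1L) %/% 2L)
  den <- median_filter2(img, median_size)
  interior <- den
  if (margin > 0L) {
    interior[] <- Inf
    rows <- (1L + margin):(d[1L] - margin)
    cols <- (1L + margin):(d[2L] - margin)
    interior[rows, cols] <- den[rows, cols]
  }
  h <- floor(window / 2)
  win_mean <- function(pos)
    mean(img[window_range(pos[1L], h, d[1L]),
             window_range(pos[2L], h, d[2L])])
  # many positions are statistically indistinguishable from the minimum
  # (Poisson noise on a flat background); consider all of them and use the
  # one whose raw window mean is lowest
  minval <- min(interior)
  tol <- 3 * sqrt(max(minval, 1))
  cand <- which(interior <= minval + tol)
  if (length(cand) > 64L)
    cand <- cand[seq(1L, length(cand), length.out = 64L)]
  cand <- arrayInd(cand, d)
  means <- apply(cand, 1L, win_mean)
  pos <- cand[which.min(means), ]
  per_px <- min(means)
  list(per_pixel = per_px, total = per_px * prod(d), position = c(pos))
}

#' Histogram-based background estimate
#'
#' The aggregate photon-arrival histogram of the whole image is median
#' filtered (running median, default 21 bins); around its minimum, the mean
#' of the *raw* histogram over a window (default 51 bins) gives the
#' background floor per microtime bin, extrapolated to the whole image by
#' multiplying by the number of bins.
#'
#' @param stack A [tcspc_stack()].
#' @param window Averaging window in bins (default 51). Shrunk with a warning
#'   when the histogram is shorter.
#' @param median_window Running-median window in bins (default 21; forced odd).
#' @return A list with `per_bin` (aggregate counts per bin), `total` and the
#'   minimum `position` (bin index).
#' @export
estimate_background_histogram <- function(stack, window = 51L,
                                          median_window = 21L) {
  stopifnot(inherits(stack, "tcspc_stack"))
  h <- aggregate_decay(stack)
  B <- length(h)
  if (window > B) {
    warning("histogram background window exceeds n_bins; shrunk to fit")
    window <- B
  }
  k <- min(median_window, B)
  if (k %% 2L == 0L) k <- k - 1L
  den <- if (k >= 3L) stats::runmed(h, k) else h
  pos <- which.min(den)
  hw <- floor(window / 2)
  per_bin <- mean(h[window_range(pos, hw, B)])
  list(per_bin = per_bin, total = per_bin * B, position = pos)
}

#' Combined, cross-checked background estimate
#'
#' Runs both the image-based and the histogram-based estimators and flags
#' them as consistent when the per-image totals agree within a factor
#' `tolerance` (default 2). The per-pixel-per-bin floor used by the phasor
#' transform comes from the chosen `source`.
#'
#' @param stack A [tcspc_stack()].
#' @param image_window,histogram_window,median_size,median_window,margin
#'   Passed to the two estimators.
#' @param tolerance Consistency factor on the ratio of totals (default 2).
#' @param source Which estimate feeds the phasor correction:
#'   `"image"` (default) or `"histogram"`.
#' @return An object of class `background_estimate` with fields
#'   `image_based`, `histogram_based` (per-image totals), `consistent`,
#'   `per_pixel_per_bin` and the raw sub-estimates.
#' @export
estimate_background <- function(stack, image_window = 21L,
                                histogram_window = 51L, median_size = 9L,
                                median_window = 21L, tolerance = 2,
                                margin = NULL,
                                source = c("image", "histogram")) {
  source <- match.arg(source)
  bi <- estimate_background_image(stack, image_window, median_size, margin)
  bh <- estimate_background_histogram(stack, histogram_window, median_window)
  npx <- stack$height * stack$width
  tiny <- 1e-3 * npx   # both estimates essentially zero photons/px
  consistent <- if (bi$total < tiny && bh$total < tiny) TRUE
                else if (bi$total <= 0 || bh$total <= 0) FALSE
                else abs(log(bi$total / bh$total)) <= log(tolerance)
  per_px <- if (source == "image") bi$per_pixel else bh$total / npx
  structure(list(image_based = bi$total, histogram_based = bh$total,
                 consistent = consistent,
                 per_pixel = per_px,
                 per_pixel_per_bin = per_px / stack$n_bins,
                 source = source, image = bi, histogram = bh,
                 tolerance = tolerance),
            class = "background_estimate")
}

#' @export
print.background_estimate <- function(x, ...) {
  cat(sprintf(
    "Background estimate: image %.4g, histogram %.4g photons/image (%s)\n",
    x$image_based, x$histogram_based,
    if (x$consistent) "consistent" else "INCONSISTENT"))
  cat(sprintf("  floor used (%s): %.4g photons/px/bin\n", x$source,
              x$per_pixel_per_bin))
  invisible(x)
}

#' Zero-background placeholder
#' @param stack A [tcspc_stack()] (for sizing only).
#' @return A `background_estimate` with a zero floor.
#' @export
zero_background <- function(stack) {
  structure(list(image_based = 0, histogram_based = 0, consistent = TRUE,
                 per_pixel = 0, per_pixel_per_bin = 0, source = "image",
                 image = NULL, histogram = NULL, tolerance = 2),
            class = "background_estimate")
}

# exact per-bin probabilities of a wrapped monoexponential decay integrated
# over bins of width d on a period of B bins
discrete_exp_pmf <- function(tau, n_bins, bin_width) {
  tl <- (seq_len(n_bins) - 1L) * bin_width
  q <- exp(-tl / tau) * (1 - exp(-bin_width / tau))
  q / sum(q)
}

# first K harmonics of a (count) histogram: P_n = sum h exp(-i n w t) / sum h
decay_harmonics <- function(h, bin_width, laser_period, K = 4L) {
  tc <- (seq_along(h) - 0.5) * bin_width
  w <- 2 * pi / laser_period
  vapply(seq_len(K), function(n) {
    sum(h * exp(-1i * n * w * tc)) / sum(h)
  }, complex(1))
}

#' Instrument response function estimate from decay harmonics
#'
#' Models the IRF as a shifted Gaussian (delay `shift`, SD `width`, both ns),
#' whose effect on the n-th harmonic of the measured decay is a factor
#' exp(-(n omega sigma)^2 / 2) exp(-i n omega t0). The delay and width,
#' together with an underlying monoexponential lifetime, are fitted by least
#' squares to the first `n_harmonics` harmonics of the background-corrected
#' aggregate histogram: the lifetime is pinned mostly by harmonic 1 and the
#' IRF by the excess phase and modulation decline of the higher harmonics.
#' The aggregate decay should be close to monoexponential (e.g. a donor-only
#' calibration acquisition); for mixtures supply the IRF explicitly via
#' [irf_estimate()].
#'
#' @param stack A registered [tcspc_stack()].
#' @param background Optional [estimate_background()] result; its per-bin
#'   floor is subtracted from the aggregate histogram first.
#' @param n_harmonics Number of harmonics used (>= 2, default 4).
#' @param min_photons Below this aggregate photon count an identity IRF is
#'   returned with a warning (default 1000).
#' @return An object of class `irf_estimate` with `shift` (ns), `width`
#'   (ns), `tau` (the nuisance monoexponential lifetime, ns) and `phasor1`
#'   (the complex IRF factor at the first harmonic).
#' @export
estimate_irf <- function(stack, background = NULL, n_harmonics = 4L,
                         min_photons = 1000) {
  stopifnot(inherits(stack, "tcspc_stack"), n_harmonics >= 2L)
  h <- aggregate_decay(stack)
  if (!is.null(background)) {
    stopifnot(inherits(background, "background_estimate"))
    npx <- stack$height * stack$width
    h <- pmax(h - background$per_pixel_per_bin * npx, 0)
  }
  if (sum(h) < min_photons) {
    warning("too few photons to estimate the IRF; returning identity IRF")
    return(irf_estimate(0, 0))
  }
  P <- stack$laser_period
  w <- 2 * pi / P
  K <- n_harmonics
  obs <- decay_harmonics(h, stack$bin_width, P, K)

  model_harmonics <- function(tau, t0, sigma) {
    q <- discrete_exp_pmf(tau, stack$n_bins, stack$bin_width)
    M <- decay_harmonics(q, stack$bin_width, P, K)
    n <- seq_len(K)
    M * exp(-(n * w * sigma)^2 / 2) * exp(-1i * n * w * t0)
  }
  objective <- function(par) {
    tau <- par[1L]; t0 <- par[2L]; sigma <- par[3L]
    if (tau <= 0.005 || tau > 10 * P || sigma < 0 || abs(t0) > P / 2)
      return(1e6)
    sum(Mod(obs - model_harmonics(tau, t0, sigma))^2)
  }
  phi1 <- -Arg(obs[1L])
  tau0 <- min(max(tan(min(max(phi1, 1e-3), pi / 2 - 1e-3)) / w, 0.05), P)
  fit <- stats::optim(c(tau0, 0, 0.05), objective, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  out <- irf_estimate(fit$par[2L], max(fit$par[3L], 0), laser_period = P)
  out$tau <- fit$par[1L]
  out$residual <- fit$value
  out
}

#' Explicit instrument response function
#'
#' A Gaussian IRF with the given delay and width; the phasor correction at
#' harmonic one is the complex division of every pixel phasor by
#' exp(-(omega sigma)^2 / 2) exp(-i omega t0).
#'
#' @param shift Delay t0 (ns).
#' @param width SD sigma (ns).
#' @param laser_period Laser period (ns) used to evaluate the first-harmonic
#'   factor; may be left `NULL` and supplied by the consumer.
#' @return An object of class `irf_estimate`.
#' @export
irf_estimate <- function(shift = 0, width = 0, laser_period = NULL) {
  stopifnot(width >= 0)
  structure(list(shift = shift, width = width, laser_period = laser_period),
            class = "irf_estimate")
}

# complex IRF factor at harmonic n for a given laser period
irf_factor <- function(irf, laser_period, n = 1L) {
  w <- 2 * pi / laser_period
  exp(-(n * w * irf$width)^2 / 2) * exp(-1i * n * w * irf$shift)
}

#' @export
print.irf_estimate <- function(x, ...) {
  cat(sprintf("Gaussian IRF: delay %.4g ns, width (SD) %.4g ns\n",
              x$shift, x$width))
  if (!is.null(x$tau))
    cat(sprintf("  (fitted against a monoexponential of tau = %.4g ns)\n",
                x$tau))
  invisible(x)
}
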
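#' First-harmonic phasor of a monoexponential lifetime
#'
#' The continuous-time closed form: g = 1 / (1 + (omega tau)^2),
#' s = omega tau / (1 + (omega tau)^2). All monoexponential decays lie on the
#' universal semicircle (g - 1/2)^2 + s^2 = 1/4.
#'
#' @param tau Lifetime(s) (ns).
#' @param omega Angular frequency (rad/ns).
#' @return A matrix with columns `g` and `s` (one row per lifetime).
#' @export
lifetime_phasor <- function(tau, omega) {
  if (any(tau < 0)) stop("'tau' must be >= 0")
  den <- 1 + (omega * tau)^2
  cbind(g = 1 / den, s = omega * tau / den)
}

#' Per-pixel first-harmonic phasor transform of a TCSPC stack
#'
#' Frames are collapsed, the background floor is subtracted per bin, and
#' every pixel's phasor is R = sum_b c_b exp(-i omega t_b) / sum_b c_b over
#' bin centers t_b, stored as (g, s) = (Re, -Im). Phasors are corrected for
#' the instrument response by complex division with the IRF's first-harmonic
#' factor. Pixels whose background-corrected total is not positive (or below
#' `min_photons`) are masked.
#'
#' @param stack A (registered) [tcspc_stack()].
#' @param background Optional [estimate_background()] result (or `NULL` for
#'   no correction).
#' @param irf Optional [irf_estimate()] (or `NULL` for an identity IRF).
#' @param min_photons Mask pixels with fewer corrected photons (default:
#'   any positive total is kept).
#' @return An object of class `phasor_image`: matrices `g`, `s`, `photons`
#'   (corrected totals clamped at zero), logical `mask` (TRUE = usable),
#'   plus `omega` and `laser_period`.
#' @export
phasor_transform <- function(stack, background = NULL, irf = NULL,
                             min_photons = NULL) {
  stopifnot(inherits(stack, "tcspc_stack"))
  w <- stack_omega(stack)
  tc <- bin_centers(stack)
  # collapse frames -> matrix (pixels x bins)
  cube <- apply(stack$counts, c(2L, 3L, 4L), sum)
  npx <- stack$height * stack$width
  M <- matrix(cube, npx, stack$n_bins)
  bg_bin <- if (is.null(background)) 0 else background$per_pixel_per_bin
  M <- M - bg_bin
  tot <- rowSums(M)
  re <- as.vector(M %*% cos(w * tc))
  im <- as.vector(M %*% sin(w * tc))
  ok <- tot > 0
  g <- s <- rep(NA_real_, npx)
  g[ok] <- re[ok] / tot[ok]
  s[ok] <- im[ok] / tot[ok]
  if (!is.null(irf)) {
    fac <- irf_factor(irf, stack$laser_period)
    z <- complex(real = g[ok], imaginary = -s[ok]) / fac
    g[ok] <- Re(z)
    s[ok] <- -Im(z)
  }
  photons <- pmax(tot, 0)
  mask <- ok
  if (!is.null(min_photons)) mask <- mask & photons >= min_photons
  structure(list(g = matrix(g, stack$height, stack$width),
                 s = matrix(s, stack$height, stack$width),
                 photons = matrix(photons, stack$height, stack$width),
                 mask = matrix(mask, stack$height, stack$width),
                 omega = w, laser_period = stack$laser_period),
            class = "phasor_image")
}

#' @export
print.phasor_image <- function(x, ...) {
  n_ok <- sum(x$mask)
  cat(sprintf("Phasor image %d x %d (%d usable px), omega = %.4g rad/ns\n",
              nrow(x$g), ncol(x$g), n_ok, x$omega))
  if (n_ok > 0) {
    wsum <- sum(x$photons[x$mask])
    cat(sprintf("  photon-weighted mean phasor: g = %.4f, s = %.4f\n",
                sum((x$g * x$photons)[x$mask]) / wsum,
                sum((x$s * x$photons)[x$mask]) / wsum))
  }
  invisible(x)
}

#' @export
plot.phasor_image <- function(x, components = NULL, ...) {
  ok <- x$mask & is.finite(x$g) & is.finite(x$s)
  graphics::plot(x$g[ok], x$s[ok], pch = ".", xlim = c(0, 1),
                 ylim = c(0, 0.6), xlab = "g (Re)", ylab = "s (Im)",
                 main = "First-harmonic phasor plot", ...)
  th <- seq(0, pi, length.out = 181L)
  graphics::lines(0.5 + 0.5 * cos(th), 0.5 * sin(th), lty = 2)
  if (!is.null(components))
    graphics::points(components[, 1L], components[, 2L], pch = 4, cex = 1.5,
                     col = 2)
  invisible(x)
}

#' Phase-lifetime map
#'
#' The apparent (phase) lifetime at the first harmonic,
#' tau_phase = tan(angle(R)) / omega = s / (g omega), per pixel. Pixels below
#' the photon threshold are masked (NA), not zero-filled.
#'
#' @param phasor A [phasor_image()].
#' @param min_photons Photon threshold for the map (default 1).
#' @return Matrix of lifetimes (ns) with NA at masked pixels.
#' @export
average_lifetime_map <- function(phasor, min_photons = 1) {
  stopifnot(inherits(phasor, "phasor_image"))
  tau <- phasor$s / (phasor$g * phasor$omega)
  tau[!phasor$mask | phasor$photons < min_photons] <- NA_real_
  tau
}

#' FRET efficiency from donor lifetimes
#'
#' E = 1 - tau_DA / tau_D, with tau_DA the donor lifetime in presence of the
#' acceptor and tau_D the unquenched donor-only lifetime.
#'
#' @param tau_da Donor lifetime with acceptor (ns), 0 <= tau_da <= tau_d.
#' @param tau_d Donor-only lifetime (ns), > 0. Default 3.71 ns (mCitrine
#'   under cryo-arrest).
#' @return FRET efficiency in `[0, 1]`; vectorized.
#' @examples
#' fret_efficiency(0.9, 3.71)   # active conformation, ~0.76
#' fret_efficiency(3.5, 3.71)   # inactive conformation, ~0.06
#' @export
fret_efficiency <- function(tau_da, tau_d = 3.71) {
  if (any(tau_d <= 0)) stop("'tau_d' must be positive")
  if (any(tau_da < 0)) stop("'tau_da' must be >= 0")
  if (any(tau_da > tau_d))
    stop("'tau_da' exceeds 'tau_d': efficiency would be negative")
  1 - tau_da / tau_d
}
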
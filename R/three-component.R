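# per-pixel constrained solve: R_obs = f_do R_do + f_act R_act + f_in R_in
# with f_do fixed and f_act + f_in = 1 - f_do, f >= 0. One free parameter,
# solved as the projection of the residual onto the act-inact chord, clamped
# to the feasible segment.
solve_fractions <- function(g, s, comp, f_do) {
  u_g <- g - f_do * comp["donor_only", "g"] - (1 - f_do) * comp["inactive", "g"]
  u_s <- s - f_do * comp["donor_only", "s"] - (1 - f_do) * comp["inactive", "s"]
  v_g <- comp["active", "g"] - comp["inactive", "g"]
  v_s <- comp["active", "s"] - comp["inactive", "s"]
  vv <- v_g^2 + v_s^2
  raw <- (u_g * v_g + u_s * v_s) / vv
  f_act <- pmin(pmax(raw, 0), 1 - f_do)
  res <- sqrt((u_g - f_act * v_g)^2 + (u_s - f_act * v_s)^2)
  list(f_act = f_act, f_inact = 1 - f_do - f_act, residual = res,
       clamped = raw < 0 | raw > 1 - f_do)
}

#' Three-component global analysis of a phasor image
#'
#' Each observed pixel phasor is modeled as the photon-fraction-weighted sum
#' of three spatially invariant component phasors: donor-only biosensor
#' (non-absorbing acceptor, unquenched lifetime), sensor in the closed
#' (active, high-FRET) conformation, and sensor in the extended (inactive)
#' conformation. The donor-only photon fraction is fixed; the split between
#' the active and inactive states is then a single constrained linear
#' parameter per pixel (non-negative fractions summing to one), solved in
#' closed form. Optionally the two conformational lifetimes are optimized
#' globally by photon-weighted least squares over all pixels (multi-start
#' Nelder-Mead over a fixed start list), with the donor-only lifetime held at
#' its calibration value.
#'
#' @param phasor A [phasor_image()], typically background/IRF corrected and
#'   denoised.
#' @param tau_donor Donor-only lifetime (ns). Default 3.71 (mCitrine under
#'   cryo-arrest).
#' @param tau_active Lifetime of the active (closed, high-FRET) conformation
#'   (ns). Default 0.9.
#' @param tau_inactive Lifetime of the inactive (extended) conformation (ns).
#'   Default 3.5.
#' @param donor_fraction Fixed photon fraction of donor-only sensor. Default
#'   0.2.
#' @param fit_lifetimes If `TRUE`, optimize (tau_active, tau_inactive)
#'   globally; otherwise use the supplied values as-is.
#' @param min_photons Pixels below this corrected photon count are excluded
#'   from the global fit and masked in the maps (default 1).
#' @return An object of class `three_component_fit`: `lifetimes` (named,
#'   ns), `donor_fraction`, `component_phasors` (3 x 2), per-pixel
#'   photon-fraction matrices `f_donor_only`, `f_active`, `f_inactive`,
#'   `residual`, `clamped` flags, `photons`, `mask`.
#' @export
fit_three_components <- function(phasor, tau_donor = 3.71, tau_active = 0.9,
                                 tau_inactive = 3.5, donor_fraction = 0.2,
                                 fit_lifetimes = FALSE, min_photons = 1) {
  stopifnot(inherits(phasor, "phasor_image"),
            donor_fraction >= 0, donor_fraction < 1,
            tau_donor > 0, tau_active > 0, tau_inactive > 0)
  w <- phasor$omega
  ok <- phasor$mask & phasor$photons >= min_photons &
    is.finite(phasor$g) & is.finite(phasor$s)
  if (sum(ok) < 3L) stop("need at least 3 informative pixels")
  g <- phasor$g[ok]; s <- phasor$s[ok]; wt <- phasor$photons[ok]

  comp_for <- function(ta, ti) {
    m <- rbind(lifetime_phasor(tau_donor, w),
               lifetime_phasor(ta, w),
               lifetime_phasor(ti, w))
    dimnames(m) <- list(c("donor_only", "active", "inactive"), c("g", "s"))
    m
  }
  taus <- c(tau_active, tau_inactive)
  if (isTRUE(fit_lifetimes)) {
    obj <- function(par) {
      if (any(par <= 0.05) || any(par > 2 * phasor$laser_period) ||
          par[1L] >= par[2L]) return(1e9)
      sol <- solve_fractions(g, s, comp_for(par[1L], par[2L]), donor_fraction)
      sum(wt * sol$residual^2)
    }
    starts <- list(c(tau_active, tau_inactive),
                   c(0.5, 2.5), c(1.5, 4.5))
    best <- NULL
    for (st in starts) {
      fit <- stats::optim(st, obj, method = "Nelder-Mead",
                          control = list(maxit = 500, reltol = 1e-10))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    taus <- best$par
  }
  comp <- comp_for(taus[1L], taus[2L])
  dims <- dim(phasor$g)
  blank <- matrix(NA_real_, dims[1L], dims[2L])
  sol <- solve_fractions(g, s, comp, donor_fraction)
  f_act <- f_in <- resid <- blank
  clamped <- matrix(FALSE, dims[1L], dims[2L])
  f_act[ok] <- sol$f_act
  f_in[ok] <- sol$f_inact
  resid[ok] <- sol$residual
  clamped[ok] <- sol$clamped
  f_do <- blank
  f_do[ok] <- donor_fraction
  if (any(sol$clamped))
    warning(sprintf(
      "%d pixel(s) outside the feasible fraction simplex; projected",
      sum(sol$clamped)))
  structure(list(
    lifetimes = c(donor_only = tau_donor, active = taus[1L],
                  inactive = taus[2L]),
    donor_fraction = donor_fraction,
    component_phasors = comp,
    f_donor_only = f_do, f_active = f_act, f_inactive = f_in,
    residual = resid, clamped = clamped,
    photons = phasor$photons, mask = ok, omega = w,
    lifetimes_fitted = isTRUE(fit_lifetimes)),
    class = "three_component_fit")
}

#' @export
print.three_component_fit <- function(x, ...) {
  cat("Three-component phasor unmixing\n")
  cat(sprintf("  lifetimes (ns): donor-only %.3g%s, active %.3g, inactive %.3g%s\n",
              x$lifetimes["donor_only"], "",
              x$lifetimes["active"], x$lifetimes["inactive"],
              if (x$lifetimes_fitted) " (globally fitted)" else " (fixed)"))
  cat(sprintf("  donor-only photon fraction (fixed): %.3g\n", x$donor_fraction))
  cat(sprintf("  pixels: %d; mean f_active = %.3f; RMS residual = %.4g\n",
              sum(x$mask), mean(x$f_active[x$mask]),
              sqrt(mean(x$residual[x$mask]^2))))
  invisible(x)
}

#' @export
summary.three_component_fit <- function(object, ...) {
  mf <- molecular_fraction_maps(object)
  out <- list(lifetimes = object$lifetimes,
              donor_fraction = object$donor_fraction,
              n_pixels = sum(object$mask),
              mean_f_active = mean(object$f_active[object$mask]),
              mean_alpha = mean(mf$alpha[object$mask]),
              rms_residual = sqrt(mean(object$residual[object$mask]^2)),
              n_clamped = sum(object$clamped, na.rm = TRUE))
  class(out) <- "summary.three_component_fit"
  out
}

#' @export
print.summary.three_component_fit <- function(x, ...) {
  cat("Three-component fit summary\n")
  print(x$lifetimes)
  cat(sprintf("  donor-only fraction %.3g | %d px | mean f_act %.3f | mean alpha %.3f\n",
              x$donor_fraction, x$n_pixels, x$mean_f_active, x$mean_alpha))
  cat(sprintf("  RMS phasor residual %.4g | %d px clamped\n",
              x$rms_residual, x$n_clamped))
  invisible(x)
}

#' @export
coef.three_component_fit <- function(object, ...) object$lifetimes

#' Molecular fractions and activity map from photon fractions
#'
#' Photon fractions weight states by their brightness; dividing by the
#' fluorescence lifetime (a measure of quantum yield) and renormalizing to 1
#' converts them to molecular fractions: m_i proportional to f_i / tau_i.
#' The active fraction alpha is renormalized to the sensing population by
#' dividing by (1 - m_donor_only).
#'
#' @param fit A [fit_three_components()] result.
#' @return A list of class `molecular_fractions` with matrices
#'   `m_donor_only`, `m_active`, `m_inactive` and `alpha`.
#' @export
molecular_fraction_maps <- function(fit) {
  stopifnot(inherits(fit, "three_component_fit"))
  tau <- fit$lifetimes
  if (any(tau <= 0)) stop("component lifetimes must be positive")
  q_do <- fit$f_donor_only / tau["donor_only"]
  q_act <- fit$f_active / tau["active"]
  q_in <- fit$f_inactive / tau["inactive"]
  tot <- q_do + q_act + q_in
  m_do <- q_do / tot
  m_act <- q_act / tot
  m_in <- q_in / tot
  alpha <- m_act / (1 - m_do)
  alpha[m_do >= 1] <- NA_real_
  structure(list(m_donor_only = m_do, m_active = m_act, m_inactive = m_in,
                 alpha = alpha),
            class = "molecular_fractions")
}

#' Photon fractions from molecular fractions (inverse conversion)
#'
#' f_i proportional to m_i * tau_i, renormalized to 1. The exact inverse of
#' the conversion in [molecular_fraction_maps()].
#'
#' @param m_donor_only,m_active,m_inactive Molecular fractions (summing to 1).
#' @param lifetimes Named vector with `donor_only`, `active`, `inactive` (ns).
#' @return A list of photon fractions `f_donor_only`, `f_active`,
#'   `f_inactive`.
#' @export
photon_fractions_from_molecular <- function(m_donor_only, m_active,
                                            m_inactive, lifetimes) {
  p_do <- m_donor_only * lifetimes[["donor_only"]]
  p_act <- m_active * lifetimes[["active"]]
  p_in <- m_inactive * lifetimes[["inactive"]]
  tot <- p_do + p_act + p_in
  list(f_donor_only = p_do / tot, f_active = p_act / tot,
       f_inactive = p_in / tot)
}
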
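#' TCSPC photon-counting stack
#'
#' A time-correlated single photon counting dataset: non-negative counts
#' indexed (frame, y, x, microtime bin), with the microtime bin width and the
#' laser repetition period in nanoseconds. The fundamental angular frequency
#' of the phasor analysis is omega = 2 pi / laser_period.
#'
#' @param counts 4-D array `[frame, y, x, bin]` of non-negative counts.
#'   Expectation-valued (non-integer) stacks from the noise-free synthetic
#'   mode are accepted.
#' @param bin_width Microtime bin width (ns).
#' @param laser_period Laser repetition period (ns); `n_bins * bin_width`
#'   must not exceed it.
#' @return An object of class `tcspc_stack`.
#' @export
tcspc_stack <- function(counts, bin_width, laser_period) {
  stopifnot(is.array(counts), length(dim(counts)) == 4L,
            bin_width > 0, laser_period > 0)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and >= 0")
  d <- dim(counts)
  if (d[4L] * bin_width > laser_period * (1 + 1e-9))
    stop("n_bins * bin_width exceeds the laser period")
  structure(list(counts = counts, bin_width = bin_width,
                 laser_period = laser_period,
                 n_frames = d[1L], height = d[2L], width = d[3L],
                 n_bins = d[4L]),
            class = "tcspc_stack")
}

#' @export
print.tcspc_stack <- function(x, ...) {
  cat(sprintf(
    "TCSPC stack: %d frame(s), %d x %d px, %d bins of %.4g ns (period %.4g ns)\n",
    x$n_frames, x$height, x$width, x$n_bins, x$bin_width, x$laser_period))
  cat(sprintf("  total photons: %.6g\n", sum(x$counts)))
  invisible(x)
}

#' Fundamental angular frequency of a stack (rad/ns)
#' @param stack A [tcspc_stack()].
#' @export
stack_omega <- function(stack) 2 * pi / stack$laser_period

#' Microtime bin centers (ns)
#' @param stack A [tcspc_stack()].
#' @export
bin_centers <- function(stack) (seq_len(stack$n_bins) - 0.5) * stack$bin_width

#' Per-frame intensity images (counts summed over microtime)
#' @param stack A [tcspc_stack()].
#' @return Array `[frame, y, x]`.
#' @export
frame_images <- function(stack) apply(stack$counts, c(1L, 2L, 3L), sum)

#' Time-summed intensity image (counts summed over frames and microtime)
#' @param stack A [tcspc_stack()].
#' @return Matrix `[y, x]`.
#' @export
intensity_image <- function(stack) apply(stack$counts, c(2L, 3L), sum)

#' Aggregate photon-arrival histogram over the whole image
#' @param stack A [tcspc_stack()].
#' @return Numeric vector of length `n_bins`.
#' @export
aggregate_decay <- function(stack) apply(stack$counts, 4L, sum)

# 2D phase correlation between two equally sized images.
# Returns the integer translation (dy, dx) such that
# img(y, x) ~ ref(y - dy, x - dx), plus a parabolic subpixel refinement.
phase_correlation_shift <- function(ref, img, eps = 1e-12) {
  stopifnot(all(dim(ref) == dim(img)))
  Fr <- stats::fft(ref)
  Fi <- stats::fft(img)
  cp <- Fr * Conj(Fi)
  m <- Mod(cp)
  cp <- cp / pmax(m, eps)
  r <- Re(stats::fft(cp, inverse = TRUE))
  pk <- arrayInd(which.max(r), dim(r))
  n <- dim(r)
  wrap <- function(i, nn) ifelse(i - 1L > nn / 2, i - 1L - nn, i - 1L)
  dy <- wrap(pk[1L], n[1L]); dx <- wrap(pk[2L], n[2L])
  # parabolic refinement on the correlation surface (computed, then rounded
  # by the caller, matching the integer-shift convention)
  sub <- c(dy, dx)
  for (ax in 1:2) {
    idx <- pk
    getv <- function(off) {
      idx2 <- idx
      idx2[ax] <- ((idx2[ax] - 1L + off) %% n[ax]) + 1L
      r[idx2[1L], idx2[2L]]
    }
    c0 <- getv(0L); cm <- getv(-1L); cp1 <- getv(1L)
    den <- cm - 2 * c0 + cp1
    if (abs(den) > eps) sub[ax] <- sub[ax] + 0.5 * (cm - cp1) / den
  }
  list(dy = dy, dx = dx, subpixel = c(dy = sub[1L], dx = sub[2L]))
}

# shift a [y, x, bin] cube by integer (dy, dx), dropping what falls outside.
# Returns the shifted cube and the number of dropped photons.
shift_cube <- function(cube, dy, dx) {
  d <- dim(cube)
  out <- array(0, d)
  ys <- seq_len(d[1L]); xs <- seq_len(d[2L])
  ys_src <- ys - dy; xs_src <- xs - dx
  oky <- ys_src >= 1L & ys_src <= d[1L]
  okx <- xs_src >= 1L & xs_src <= d[2L]
  if (any(oky) && any(okx))
    out[ys[oky], xs[okx], ] <- cube[ys_src[oky], xs_src[okx], ]
  list(cube = out, dropped = sum(cube) - sum(out))
}

#' Register a photon-counting stack against its first frame
#'
#' Rigid, translation-only drift correction. Per-frame intensity images
#' (counts summed over microtime) are compared with the first frame by phase
#' correlation; the estimated drift is rounded to the nearest integer pixel
#' and each photon of the frame is shifted by the opposite amount. Photons
#' that fall outside the field of view defined by the first frame are
#' dropped, so the registered stack never gains counts.
#'
#' @param stack A [tcspc_stack()].
#' @return A list of class `registered_stack` with elements `stack` (the
#'   registered [tcspc_stack()]), `drift` (estimated per-frame drift, frames
#'   x (dy, dx), subpixel), `applied` (integer shifts actually applied) and
#'   `dropped` (photons removed, total and per frame).
#' @export
register_stack <- function(stack) {
  stopifnot(inherits(stack, "tcspc_stack"))
  nf <- stack$n_frames
  imgs <- frame_images(stack)
  ref <- if (nf == 1L) matrix(imgs, stack$height, stack$width)
         else imgs[1L, , ]
  drift <- matrix(0, nf, 2L, dimnames = list(NULL, c("dy", "dx")))
  applied <- matrix(0L, nf, 2L, dimnames = list(NULL, c("dy", "dx")))
  dropped <- numeric(nf)
  new_counts <- stack$counts
  if (nf > 1L) for (f in 2:nf) {
    frame_img <- imgs[f, , ]
    if (sum(frame_img) == 0) {
      warning(sprintf("frame %d has no photons; shift (0,0) assumed", f))
      next
    }
    pc <- phase_correlation_shift(ref, frame_img)
    drift[f, ] <- -pc$subpixel           # estimated drift of frame f vs 1
    corr <- as.integer(round(c(pc$dy, pc$dx)))  # integer correction to apply
    applied[f, ] <- corr
    if (any(corr != 0L)) {
      res <- shift_cube(stack$counts[f, , , , drop = TRUE], corr[1L], corr[2L])
      new_counts[f, , , ] <- res$cube
      dropped[f] <- res$dropped
    }
  }
  structure(list(stack = tcspc_stack(new_counts, stack$bin_width,
                                     stack$laser_period),
                 drift = drift, applied = applied,
                 dropped = sum(dropped), dropped_per_frame = dropped),
            class = "registered_stack")
}

#' @export
print.registered_stack <- function(x, ...) {
  cat(sprintf("Registered TCSPC stack (%d frames), %g photon(s) dropped\n",
              x$stack$n_frames, x$dropped))
  print(cbind(drift = x$drift, applied = x$applied))
  invisible(x)
}
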
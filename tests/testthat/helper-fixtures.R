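# shared fixture builders; everything is generated in code at test time

kB <- 1.380649e-23

# a small monoexponential stack (optionally with IRF and flat background),
# built directly from the generator in donor-only mode
mono_stack <- function(tau = 3.5, photons = 5000, n_px = 8L, n_bins = 256L,
                       period = 12.5, irf_shift = 0, irf_width = 0,
                       background_rate = 0, noise_free = TRUE, seed = 1L,
                       n_frames = 1L) {
  spec <- scene_spec(width = n_px, height = n_px, n_frames = n_frames,
                     n_bins = n_bins, laser_period = period,
                     photons_per_pixel = photons,
                     background_rate = background_rate,
                     lifetimes = c(donor_only = tau, active = 0.9,
                                   inactive = 3.5),
                     donor_fraction = 1,
                     blobs = data.frame(cy = n_px / 2, cx = n_px / 2,
                                        radius = 2 * n_px, alpha = 0),
                     irf_shift = irf_shift, irf_width = irf_width,
                     seed = seed)
  generate_tcspc_stack(spec, noise_free = noise_free)
}

# build a tcspc_stack from an explicit per-pixel-per-bin expectation matrix
stack_from_decays <- function(decays, bin_width, period, ny, nx) {
  # decays: matrix (n_px x n_bins), row i -> pixel i (column-major)
  B <- ncol(decays)
  counts <- array(0, c(1L, ny, nx, B))
  for (b in seq_len(B)) counts[1L, , , b] <- matrix(decays[, b], ny, nx)
  tcspc_stack(counts, bin_width, period)
}

# analytic valley contrast of the true two-Gaussian mixture (independent
# scan, no package internals)
analytic_contrast <- function(d, sigma, split = 0.5, n = 20001L) {
  x <- seq(-d / 2 - 5 * sigma, d / 2 + 5 * sigma, length.out = n)
  f <- split * dnorm(x, -d / 2, sigma) + (1 - split) * dnorm(x, d / 2, sigma)
  df <- diff(f)
  pk <- which(df[-1] <= 0 & df[-length(df)] > 0) + 1L
  if (length(pk) < 2L) return(0)
  top2 <- sort(pk[order(f[pk], decreasing = TRUE)[1:2]])
  1 - min(f[top2[1L]:top2[2L]]) / max(f[top2])
}
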
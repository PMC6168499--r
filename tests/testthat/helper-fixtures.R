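# Shared fixtures: all built in code, scaled for fast iteration.

# A fast-relaxing variant of the standard device (many more connecting
# channels -> low R_T -> pressure decay time constant of ~1 h), so closed
# forms and the ODE integration can be compared over a meaningful decay.
fast_network <- function(overflow = TRUE) {
  default_gradient_device(
    overflow = overflow,
    connecting = channel_segment(10, 7, 2000, "connecting array",
                                 n_parallel = 25000))
}

# Independent >= 20-term series oracle for the rectangular-duct resistance,
# written directly from the Fourier solution (kept separate from the
# implementation on purpose).
duct_resistance_series_oracle <- function(w_um, h_um, L_um, mu = 0.7e-3,
                                          terms = 20) {
  w <- w_um * 1e-6; h <- h_um * 1e-6; L <- L_um * 1e-6
  if (h > w) { tmp <- w; w <- h; h <- tmp }
  n <- seq(1, by = 2, length.out = terms)
  f <- 1 - (192 * h / (pi^5 * w)) * sum(tanh(n * pi * w / (2 * h)) / n^5)
  12 * mu * L / (w * h^3 * f)
}

# Ideal-circle / rough-contour rendered crop via the package's renderer.
rendered_disk <- function(radius, amplitude = 0, crop_px = 160, seed = 7,
                          noise_sd = 0.03, contour_seed = 1) {
  gradspheroid:::render_crop(radius, amplitude, viable = 1,
                             contour_seed = contour_seed, crop_px = crop_px,
                             pixel_scale = 1, noise_sd = noise_sd,
                             endpoint = TRUE, rng_seed = seed)
}

# Star-convex ground-truth pixel mask for a contour produced by
# spheroid_contour (radial comparison at pixel centres).
contour_mask <- function(xy, crop_px) {
  cx <- (crop_px + 1) / 2
  px <- (seq_len(crop_px) - cx)
  X <- matrix(px, crop_px, crop_px, byrow = TRUE)
  Y <- matrix(px, crop_px, crop_px)
  th <- atan2(Y, X)
  r_ref <- sqrt(xy[, 1]^2 + xy[, 2]^2)
  th_ref <- atan2(xy[, 2], xy[, 1])
  o <- order(th_ref)
  fr <- stats::approxfun(c(th_ref[o] - 2 * pi, th_ref[o], th_ref[o] + 2 * pi),
                         rep(r_ref[o], 3))
  sqrt(X^2 + Y^2) <= matrix(fr(as.vector(th)), crop_px, crop_px)
}

# Small calcein field (literature diffusivity) on a constant flow, used by
# gradient-summary tests that don't need the full network run.
quick_calcein_field <- function(duration = 2 * 3600, grid_spacing = 40) {
  calc <- compound("calcein", 623, diffusion_coefficient = 4.0e-10,
                   source_concentration = 100)
  simulate_gradient_experiment(calc, duration, grid_spacing = grid_spacing,
                               save_every = 1800)
}

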
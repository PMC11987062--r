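# Small scene builders shared across tests.

# One emitter in a small field; noiseless by default and delta PSF, so the
# emitter trace lands in exactly one pixel.
tiny_scene <- function(height = 24, width = 24, theta = pi / 4, alpha = 0.6,
                       base = 1000, psf_sigma = 0, bg = 0, noise = FALSE,
                       seed = 1L, f = 0.21, K = 72L) {
  synthetic_scene(
    height, width,
    emitters = list(nv_emitter(row = 11, col = 13, alpha = alpha,
                               theta = theta, base_intensity = base)),
    background = background_spec("constant", mean_level = bg),
    acquisition = acquisition_config(n_frames = K, mod_frequency = f,
                                     psf_sigma = psf_sigma,
                                     read_noise_sigma = if (noise) 5 else 0,
                                     poisson_noise = noise, seed = seed))
}

# Background-only noisy scene (no emitters).
noise_scene <- function(height = 32, width = 32, bg = 500, seed = 1L) {
  synthetic_scene(
    height, width, emitters = list(),
    background = background_spec("constant", mean_level = bg),
    acquisition = acquisition_config(read_noise_sigma = 5,
                                     poisson_noise = TRUE, seed = seed))
}

# Synthetic NV-like trace with additive Gaussian noise at a given
# amplitude-to-noise-sigma ratio.
nv_like_trace <- function(K = 72, f = 0.21, a_over_sigma = 4, sigma = 25,
                          phase = NULL) {
  if (is.null(phase)) phase <- stats::runif(1, -pi, pi)
  a <- a_over_sigma * sigma
  10 * a + a * cos(2 * pi * f * (0:(K - 1)) + phase) + stats::rnorm(K, 0, sigma)
}
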
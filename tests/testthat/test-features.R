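test_that("detrend removes mean and optionally a linear ramp", {
  expect_equal(detrend(rep(5, 20)), rep(0, 20))
  k <- 0:71
  tr <- 3 + 2 * sin(2 * pi * 0.25 * k)   # integer number of cycles
  expect_lt(abs(mean(detrend(tr))), 1e-12)
  expect_equal(detrend(tr), 2 * sin(2 * pi * 0.25 * k), tolerance = 1e-12)
  ramp <- 1 + 0.5 * k
  expect_lt(max(abs(detrend(ramp, linear = TRUE))), 1e-9)
  expect_error(detrend(1:5), "too short")
})

test_that("periodogram peak is exact on bin-centered sines and refined off-bin", {
  K <- 72
  k <- 0:(K - 1)
  # bin-centered: exact frequency, near-total power concentration
  p <- periodogram_peak(cos(2 * pi * (15 / K) * k + 0.4))
  expect_equal(p$f_hat, 15 / K, tolerance = 1e-9)
  expect_gt(p$peak_power_fraction, 0.999)
  # off-bin sweep: within half a bin after quadratic interpolation
  errs <- sapply(seq(0.06, 0.44, length.out = 100), function(f0)
    abs(periodogram_peak(cos(2 * pi * f0 * k + 0.3))$f_hat - f0))
  expect_lt(max(errs), 0.5 / K)
  expect_error(periodogram_peak(rep(2, K)), "zero AC power")
})

test_that("white-noise peak-power fraction matches a brute-force Monte Carlo", {
  K <- 72
  # independent oracle: direct max-share of one-sided periodogram ordinates
  oracle_frac <- function(x) {
    p <- Mod(stats::fft(x - mean(x)))^2
    one <- p[2:(K / 2 + 1)]
    max(p[2:((K - 1) %/% 2 + 1)]) / sum(one)
  }
  set.seed(31)
  oracle <- replicate(3000, oracle_frac(rnorm(K)))
  set.seed(77)
  ours <- replicate(3000, periodogram_peak(rnorm(K))$peak_power_fraction)
  expect_lt(abs(quantile(ours, 0.95) - quantile(oracle, 0.95)) /
              quantile(oracle, 0.95), 0.02)
})

test_that("fixed-frequency sine fit recovers noiseless parameters exactly", {
  K <- 72
  k <- 0:(K - 1)
  tr <- 40 + 100 * cos(2 * pi * 0.21 * k - 1.1)
  fit <- fit_sine_fixed(tr, 0.21)
  expect_equal(fit$amplitude, 100, tolerance = 1e-9)
  expect_equal(fit$phase, -1.1, tolerance = 1e-9)
  expect_equal(fit$offset, 40, tolerance = 1e-9)
  expect_equal(fit$accuracy, 1, tolerance = 1e-12)
  expect_error(fit_sine_fixed(tr, 0.6), "0, 0.5")
})

test_that("fitting accuracy behaves as variance explained", {
  K <- 72
  set.seed(21)
  # null: mean accuracy ~ 2/(K-1) on pure white noise
  null_acc <- replicate(4000, fit_sine_fixed(rnorm(K), 0.21)$accuracy)
  expect_lt(abs(mean(null_acc) - 2 / (K - 1)) / (2 / (K - 1)), 0.1)
  # moderate SNR: mean accuracy ~ (A^2/2) / (A^2/2 + sigma^2) = 8/9 at A/s=4
  set.seed(22)
  acc4 <- replicate(1500, fit_sine_fixed(nv_like_trace(a_over_sigma = 4),
                                         0.21)$accuracy)
  expect_lt(abs(mean(acc4) - 8 / 9), 0.02)
  # R^2 is invariant to affine intensity rescaling
  tr <- nv_like_trace(a_over_sigma = 3)
  expect_equal(fit_sine_fixed(tr, 0.21)$accuracy,
               fit_sine_fixed(7.5 * tr + 1000, 0.21)$accuracy,
               tolerance = 1e-12)
})

test_that("amplitude estimator is unbiased at high SNR", {
  set.seed(33)
  sigma <- 25
  a <- 10 * sigma
  amps <- replicate(4000,
    fit_sine_fixed(nv_like_trace(a_over_sigma = 10, sigma = sigma),
                   0.21)$amplitude)
  expect_lt(abs(mean(amps) - a) / a, 0.01)
})

test_that("free-frequency fit recovers frequency and dominates the fixed fit", {
  K <- 72
  k <- 0:(K - 1)
  # noiseless recovery across off-bin frequencies
  errs <- sapply(seq(0.07, 0.43, length.out = 25), function(f0)
    abs(fit_sine_free(2 + cos(2 * pi * f0 * k + 0.3))$frequency - f0))
  expect_lt(max(errs), 1e-4)
  # constant trace degenerates gracefully
  flat <- fit_sine_free(rep(4, K))
  expect_equal(flat$amplitude, 0)
  expect_equal(flat$accuracy, 0)
  # optimization dominance over the fixed fit, noise and signal traces alike
  set.seed(8)
  for (i in 1:120) {
    tr <- if (i %% 2) rnorm(K) else nv_like_trace(a_over_sigma = 2)
    expect_gte(fit_sine_free(tr)$accuracy,
               fit_sine_fixed(tr, 0.21)$accuracy - 1e-10)
  }
})

test_that("white-noise free-fit frequencies are uniformly spread over bins", {
  K <- 72
  set.seed(12)
  bins <- replicate(2500, periodogram_peak(rnorm(K))$peak_bin)
  p <- chisq.test(tabulate(bins, (K - 2) %/% 2))$p.value
  expect_gt(p, 0.01)
})

test_that("extract_features separates NV from background and is NaN-safe", {
  # noiseless delta-PSF scene: NV pixel accuracy 1, everything else 0
  gen <- generate_scene(tiny_scene(psf_sigma = 0, bg = 0, noise = FALSE))
  feats <- extract_features(gen$stack)
  expect_equal(feats$accuracy[gen$truth$nv_mask], 1, tolerance = 1e-9)
  expect_true(all(feats$accuracy[!gen$truth$nv_mask] == 0))
  # dead pixel handling
  stack <- gen$stack
  stack$data[2, 2, ] <- 0
  feats <- extract_features(stack)
  expect_equal(feats$accuracy[2, 2], 0)
  # free mode records per-pixel frequencies
  featsf <- extract_features(gen$stack, mode = "free")
  r <- which(gen$truth$nv_mask, arr.ind = TRUE)
  expect_equal(featsf$frequency[r], 0.21, tolerance = 1e-4)
})

test_that("preset feature maps reproduce the published accuracy separation", {
  # stained-cell analog: NV median accuracy > 0.8, non-NV 95th pct < 0.15
  gen <- generate_scene(scenario_preset("stained_cell", height = 128,
                                        width = 128, n_emitters = 4, seed = 5))
  feats <- extract_features(gen$stack)
  expect_gt(median(feats$accuracy[gen$truth$nv_mask]), 0.8)
  expect_lt(quantile(feats$accuracy[!gen$truth$nv_mask], 0.95), 0.15)
  # LED analog (high SNR): NV accuracy > 0.85, non-NV mean < 0.05
  gen <- generate_scene(scenario_preset("led", height = 128, width = 128,
                                        n_emitters = 4, seed = 5))
  feats <- extract_features(gen$stack)
  expect_gt(median(feats$accuracy[gen$truth$nv_mask]), 0.85)
  expect_lt(mean(feats$accuracy[!gen$truth$nv_mask]), 0.05)
})
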
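test_that("excitation efficiency follows the polarization-selection rule", {
  # out-of-plane axis: no modulation at all
  beta <- seq(0, pi, length.out = 50)
  expect_equal(excitation_efficiency(beta, 0.3, pi / 2), rep(1, 50))
  # in-plane axis: extremes of cos^2
  expect_equal(excitation_efficiency(0.8, 0.8, 0), 0)
  expect_equal(excitation_efficiency(0.8 + pi / 2, 0.8, 0), 1)
  # theta = pi/4: closed-form expansion 1 - cos^2(theta)/2 * (1 + cos 2(b-a));
  # grid aligned with alpha so the extrema are sampled exactly
  b <- seq(0, pi, length.out = 1001)[-1001]
  eff <- excitation_efficiency(b, 0, pi / 4)
  expect_equal(mean(eff), 0.75, tolerance = 1e-12)
  expect_equal(max(eff) - min(eff), 0.5, tolerance = 1e-9)
  # period pi in beta
  expect_equal(excitation_efficiency(0.37, 1.1, 0.5),
               excitation_efficiency(0.37 + pi, 1.1, 0.5))
})

test_that("nv_trace matches its closed-form sine parameters", {
  acq <- acquisition_config(n_frames = 72, mod_frequency = 0.21)
  # out-of-plane: constant trace at base intensity
  em <- nv_emitter(5, 5, 0.4, pi / 2, 100)
  expect_equal(nv_trace(em, acq), rep(100, 72))
  # in-plane axis aligned with the sweep origin: the K = 72 sweep at
  # f = 0.21 samples both extrema exactly (k = 0 and k = 50), so full
  # modulation runs from 0 to base
  em <- nv_emitter(5, 5, 0, 0, 100)
  tr <- nv_trace(em, acq)
  expect_equal(min(tr), 0, tolerance = 1e-9)
  expect_equal(max(tr), 100, tolerance = 1e-9)
  # arbitrary emitter: trace equals c + A cos(2 pi f k + phi) exactly
  em <- nv_emitter(5, 5, 1.234, 0.7, 850)
  p <- nv_trace_params(em, acq)
  k <- 0:71
  model <- p$offset + p$amplitude * cos(2 * pi * p$frequency * k + p$phase)
  expect_equal(nv_trace(em, acq), model, tolerance = 1e-9)
  expect_true(all(nv_trace(em, acq) >= 0))
})

test_that("trace modulation contrast spans the FND range over theta", {
  acq <- acquisition_config()
  contr <- sapply(seq(0, pi / 2, length.out = 181), function(th)
    modulation_contrast(nv_trace(nv_emitter(1, 1, 0.3, th, 100), acq)))
  # cos^2(theta) sweeps [0, 1], covering the published 20-68% FND range
  expect_lt(min(contr), 0.20)
  expect_gt(max(contr), 0.68)
  # contrast equals the closed form cos^2 theta implied by the excitation
  # rule (alpha = 0 so the discrete sweep samples the extrema exactly)
  th <- 0.6
  expect_equal(
    modulation_contrast(nv_trace(nv_emitter(1, 1, 0, th, 100), acq)),
    cos(th)^2, tolerance = 1e-9)
})

test_that("modulation contrast definition and edge cases", {
  expect_equal(modulation_contrast(rep(7, 20)), 0)
  expect_equal(modulation_contrast(c(50, 75, 100)), 0.5)
  expect_equal(modulation_contrast(c(0, 50, 100)), 1)
  expect_error(modulation_contrast(rep(0, 10)), "undefined")
})

test_that("config constructors reject invalid physics", {
  expect_error(acquisition_config(mod_frequency = 0.5), "Nyquist")
  expect_error(acquisition_config(n_frames = 4), ">= 8")
  expect_error(nv_emitter(1, 1, -0.1, 0.2, 10), "alpha")
  expect_error(nv_emitter(1, 1, 0.1, 2, 10), "theta")
  expect_error(nv_emitter(1, 1, 0.1, 0.2, -1), "base_intensity")
})

test_that("generate_scene renders emitters, background and noise correctly", {
  # zero emitters, zero background, no noise -> all-zero stack, empty mask
  sc <- synthetic_scene(16, 16, list(),
                        background_spec("constant", 0),
                        acquisition_config(read_noise_sigma = 0,
                                           poisson_noise = FALSE))
  gen <- generate_scene(sc)
  expect_true(all(gen$stack$data == 0))
  expect_false(any(gen$truth$nv_mask))

  # delta PSF, no noise: exactly one nonzero pixel whose trace is nv_trace
  sc <- tiny_scene(psf_sigma = 0, bg = 0, noise = FALSE)
  gen <- generate_scene(sc)
  nz <- which(apply(gen$stack$data, c(1, 2), max) > 0)
  expect_length(nz, 1)
  expect_equal(gen$stack$data[11 + 1, 13 + 1, ],
               nv_trace(sc$emitters[[1]], sc$acquisition), tolerance = 1e-9)
  expect_equal(sum(gen$truth$nv_mask), 1)

  # noiseless per-pixel traces match the ground-truth sine parameters
  sc <- tiny_scene(psf_sigma = 1.1, bg = 0, noise = FALSE)
  gen <- generate_scene(sc)
  tr <- gen$truth
  k <- 0:(dim(gen$stack$data)[3] - 1)
  px <- which(tr$nv_mask, arr.ind = TRUE)
  for (i in seq_len(nrow(px))) {
    r <- px[i, 1]; c <- px[i, 2]
    model <- tr$offset[r, c] +
      tr$amplitude[r, c] * cos(2 * pi * 0.21 * k + tr$phase[r, c])
    expect_equal(gen$stack$data[r, c, ], model, tolerance = 1e-9)
  }
})

test_that("generation is bit-reproducible for a fixed seed", {
  g1 <- generate_scene(scenario_preset("stained_cell", height = 64, width = 64,
                                       n_emitters = 3, seed = 11))
  g2 <- generate_scene(scenario_preset("stained_cell", height = 64, width = 64,
                                       n_emitters = 3, seed = 11))
  expect_identical(g1$stack$data, g2$stack$data)
  expect_identical(g1$truth$nv_mask, g2$truth$nv_mask)
})

test_that("stack mean decomposes into rendered signal plus background", {
  sc <- scenario_preset("dye", height = 64, width = 64, n_emitters = 2,
                        seed = 4)
  gen <- generate_scene(sc)
  mean_img <- rowMeans(gen$stack$data, dims = 2)
  expected <- gen$truth$offset + gen$truth$background_mean
  # Monte-Carlo error of a K-frame Poisson mean ~ sqrt(B/K) per pixel
  err <- (mean_img - expected) / sqrt(pmax(expected, 1) / dim(gen$stack$data)[3])
  expect_lt(abs(mean(err)), 0.05)
  expect_lt(max(abs(err)), 6)
})

test_that("noisy background pixels are white (flat autocorrelation)", {
  gen <- generate_scene(noise_scene(seed = 2))
  K <- dim(gen$stack$data)[3]
  bound <- 3 / sqrt(K)
  for (px in list(c(3, 5), c(10, 20), c(30, 7), c(17, 17))) {
    ac <- stats::acf(gen$stack$data[px[1], px[2], ], lag.max = 10,
                     plot = FALSE)$acf[-1]
    expect_true(all(abs(ac) < bound))
  }
})

test_that("scene memory budget is enforced", {
  sc <- synthetic_scene(2000, 2000, list(), background_spec("constant", 10),
                        acquisition_config(n_frames = 72))
  expect_error(generate_scene(sc), "memory budget")
})

test_that("presets calibrate raw SBR to the printed pre-enhancement values", {
  targets <- c(led = 1.58, dye = 2.27, stained_cell = 2.61, embryo = 1.92,
               odmr_cell = 20 * log10(4 / 3))
  for (nm in names(targets)) {
    gen <- generate_scene(scenario_preset(nm, seed = 7))
    raw <- sbr_db(rowMeans(gen$stack$data, dims = 2), gen$truth$nv_mask)
    expect_lt(abs(raw$sbr_db - targets[[nm]]), 0.1,
              label = sprintf("raw SBR deviation (%s)", nm))
    # sparse NV support: at most a few hundred pixels in a 256^2 field
    expect_lt(sum(gen$truth$nv_mask), 500)
  }
  expect_error(scenario_preset("lava_lamp"), "arg")
})

test_that("odmr_cell preset fixes background:signal at 3:1 on emitter pixels", {
  gen <- generate_scene(scenario_preset("odmr_cell", seed = 3))
  s <- mean(gen$truth$offset[gen$truth$nv_mask])
  b <- mean(gen$truth$background_mean[gen$truth$nv_mask])
  expect_equal(b / s, 3, tolerance = 1e-9)
})
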
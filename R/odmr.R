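#' ODMR spectrum container
#'
#' Microwave-frequency-indexed fluorescence intensities: baseline high, dip
#' low near the NV zero-field resonance (~2870 MHz).
#'
#' @param mw_frequencies Strictly increasing microwave frequencies, MHz
#'   (>= 15 points spanning the dip).
#' @param intensities Nonnegative intensities, counts.
#' @param n_averages Number of independent measurements averaged.
#' @return An object of class `odmr_spectrum`.
#' @export
odmr_spectrum <- function(mw_frequencies, intensities, n_averages = 1L) {
  if (length(mw_frequencies) < 15)
    stop("need at least 15 microwave frequency points spanning the dip")
  if (length(intensities) != length(mw_frequencies))
    stop("intensities and mw_frequencies lengths differ")
  if (any(diff(mw_frequencies) <= 0))
    stop("mw_frequencies must be strictly increasing")
  structure(list(mw_frequencies = as.numeric(mw_frequencies),
                 intensities = as.numeric(intensities),
                 n_averages = as.integer(n_averages)),
            class = "odmr_spectrum")
}

# Unit-peak Lorentzian centered at c with full width at half maximum w.
.lorentz <- function(nu, center, fwhm) {
  (fwhm / 2)^2 / ((nu - center)^2 + (fwhm / 2)^2)
}

#' Simulate an ODMR spectrum
#'
#' `intensity(nu) = S * (1 - C * L(nu)) + B + noise` with `L` a unit-peak
#' Lorentzian. Unmodulated background light `B` dilutes the measured
#' contrast to `C * S / (S + B)` (the contrast-dilution identity).
#'
#' @param true_contrast Intrinsic ODMR contrast `C` in (0, 1).
#' @param center Dip center, MHz.
#' @param fwhm Dip full width at half maximum, MHz.
#' @param signal_level NV signal level `S`, counts.
#' @param background_level Background level `B`, counts.
#' @param noise_sigma Gaussian noise sigma, counts.
#' @param seed Integer seed.
#' @param mw_frequencies Frequency grid, MHz (default: center +/- 4 FWHM,
#'   81 points).
#' @return An [odmr_spectrum()].
#' @export
simulate_odmr <- function(true_contrast, center = 2870, fwhm = 10,
                          signal_level = 1000, background_level = 0,
                          noise_sigma = 0, seed = 1L,
                          mw_frequencies = NULL) {
  stopifnot(true_contrast > 0, true_contrast < 1, fwhm > 0, signal_level > 0,
            background_level >= 0, noise_sigma >= 0)
  if (is.null(mw_frequencies))
    mw_frequencies <- seq(center - 4 * fwhm, center + 4 * fwhm, length.out = 81)
  set.seed(seed)
  y <- signal_level * (1 - true_contrast * .lorentz(mw_frequencies, center, fwhm)) +
    background_level
  if (noise_sigma > 0) y <- y + stats::rnorm(length(y), 0, noise_sigma)
  odmr_spectrum(mw_frequencies, y)
}

#' Per-pixel ODMR image series
#'
#' Builds an `H x W x M` intensity array over `M` microwave frequencies from
#' a per-pixel NV signal image and background image: every pixel follows
#' `S_px * (1 - C * L(nu)) + B_px (+ noise)`. This is the fixture for
#' classifier-gated spectrum aggregation.
#'
#' @param signal_image `H x W` NV signal image, counts (0 off-emitter).
#' @param background_image `H x W` background image (or scalar), counts.
#' @param true_contrast Intrinsic contrast `C` in (0, 1).
#' @param center,fwhm Dip center and width, MHz.
#' @param mw_frequencies Frequency grid, MHz.
#' @param noise_sigma Gaussian noise sigma, counts.
#' @param seed Integer seed.
#' @return List with `series` (`H x W x M` array) and `mw_frequencies`.
#' @export
odmr_image_series <- function(signal_image, background_image, true_contrast,
                              center = 2870, fwhm = 10,
                              mw_frequencies = seq(2830, 2910, by = 1),
                              noise_sigma = 0, seed = 1L) {
  H <- nrow(signal_image); W <- ncol(signal_image)
  if (length(background_image) == 1)
    background_image <- matrix(background_image, H, W)
  set.seed(seed)
  L <- .lorentz(mw_frequencies, center, fwhm)
  series <- array(0, dim = c(H, W, length(mw_frequencies)))
  for (m in seq_along(mw_frequencies)) {
    frame <- signal_image * (1 - true_contrast * L[m]) + background_image
    if (noise_sigma > 0)
      frame <- frame + matrix(stats::rnorm(H * W, 0, noise_sigma), H, W)
    series[, , m] <- frame
  }
  list(series = series, mw_frequencies = mw_frequencies)
}

#' Aggregate a per-pixel ODMR series over a pixel mask
#'
#' Per microwave frequency, the spectrum intensity is the mean over the mask
#' pixels only. Gating on the classifier's NV mask rejects background pixels
#' and undoes their contrast dilution; the raw comparison spectrum uses a
#' wider aperture including background pixels (see [aperture_mask()]).
#'
#' @param series `H x W x M` array (or the list from [odmr_image_series()]).
#' @param mask Nonempty logical `H x W` matrix.
#' @param mw_frequencies Frequency grid, MHz (taken from `series` when it is
#'   an [odmr_image_series()] result).
#' @return An [odmr_spectrum()].
#' @export
enhanced_spectrum <- function(series, mask, mw_frequencies = NULL) {
  if (is.list(series) && !is.null(series$series)) {
    if (is.null(mw_frequencies)) mw_frequencies <- series$mw_frequencies
    series <- series$series
  }
  d <- dim(series)
  if (length(d) != 3) stop("series must be an H x W x M array")
  if (!all(dim(mask) == d[1:2])) stop("mask geometry does not match the series")
  if (!any(mask)) stop("mask is empty: nothing to aggregate")
  if (is.null(mw_frequencies)) stop("mw_frequencies required")
  y <- vapply(seq_len(d[3]), function(m) mean(series[, , m][mask]), 0)
  odmr_spectrum(mw_frequencies, y)
}

#' Dilate a mask into a detection aperture
#'
#' Union of all pixels within Euclidean distance `radius` of a mask pixel.
#' With `radius = 1` each isolated NV pixel grows into a 5-pixel cross - the
#' fixed aperture used as the uncorrected ("raw") aggregation region.
#'
#' @param mask Logical matrix.
#' @param radius Dilation radius, pixels.
#' @return Logical matrix.
#' @export
aperture_mask <- function(mask, radius = 1) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(FALSE, H, W)
  r <- floor(radius)
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  idx <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(offs))) {
    rr <- idx[, 1] + offs$dr[i]; cc <- idx[, 2] + offs$dc[i]
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    out[cbind(rr[ok], cc[ok])] <- TRUE
  }
  out
}

#' Lorentzian dip fit of an ODMR spectrum
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `baseline - sum_i depth_i * L_i(nu)` with unit-peak Lorentzians,
#' initialized from the deepest local minima. Contrast is dip depth over
#' baseline. Parameter confidence intervals come from the local curvature
#' (Wald) approximation at the reported level.
#'
#' @param spectrum An [odmr_spectrum()].
#' @param n_dips 1 or 2.
#' @param conf_level Confidence level for parameter intervals (default 0.91).
#' @return List of `lorentz_fit` objects sorted by center, each with
#'   `center`, `fwhm`, `contrast`, `baseline`, `fit_r2`, and `ci` (half
#'   widths for center/fwhm/contrast).
#' @export
fit_lorentzian <- function(spectrum, n_dips = 1, conf_level = 0.91) {
  stopifnot(inherits(spectrum, "odmr_spectrum"), n_dips %in% c(1, 2))
  x <- spectrum$mw_frequencies
  y <- spectrum$intensities
  if (length(x) < 5 * n_dips + 5) stop("too few points for a stable fit")
  b0 <- stats::quantile(y, 0.9, names = FALSE)
  noise_est <- stats::mad(diff(y)) / sqrt(2)
  depth0 <- b0 - min(y)
  if (depth0 <= 0 || depth0 < 4 * noise_est)
    stop("no significant dip: Lorentzian fit does not converge")
  ys <- if (length(y) >= 7) stats::runmed(y, 5) else y
  ord <- order(ys)
  centers0 <- x[ord[1]]
  if (n_dips == 2) {
    span <- diff(range(x))
    sep <- which(abs(x[ord] - centers0) > span / 6)[1]
    if (is.na(sep)) stop("could not locate two distinct dips")
    centers0 <- c(centers0, x[ord[sep]])
  }
  w0 <- diff(range(x)) / 8
  start <- list(b = b0)
  lower <- c(b = 0)
  upper <- c(b = Inf)
  for (i in seq_len(n_dips)) {
    start[[paste0("d", i)]] <- depth0 / n_dips
    start[[paste0("c", i)]] <- centers0[i]
    start[[paste0("w", i)]] <- w0
    lower <- c(lower, 0, min(x), diff(range(x)) / length(x))
    upper <- c(upper, Inf, max(x), 2 * diff(range(x)))
  }
  form <- if (n_dips == 1) {
    y ~ b - d1 * (w1 / 2)^2 / ((x - c1)^2 + (w1 / 2)^2)
  } else {
    y ~ b - d1 * (w1 / 2)^2 / ((x - c1)^2 + (w1 / 2)^2) -
      d2 * (w2 / 2)^2 / ((x - c2)^2 + (w2 / 2)^2)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = data.frame(x = x, y = y), start = start,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Lorentzian fit did not converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA, length(cf)))
  names(se) <- names(cf)
  z <- stats::qnorm((1 + conf_level) / 2)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  fits <- lapply(seq_len(n_dips), function(i) {
    d <- cf[paste0("d", i)]; b <- cf["b"]
    contrast_se <- if (all(is.finite(se[c(paste0("d", i), "b")]))) {
      # first-order propagation for d/b (correlation ignored)
      (d / b) * sqrt((se[paste0("d", i)] / d)^2 + (se["b"] / b)^2)
    } else NA_real_
    structure(list(center = unname(cf[paste0("c", i)]),
                   fwhm = unname(cf[paste0("w", i)]),
                   contrast = unname(d / b),
                   baseline = unname(b),
                   fit_r2 = r2,
                   conf_level = conf_level,
                   ci = c(center = unname(z * se[paste0("c", i)]),
                          fwhm = unname(z * se[paste0("w", i)]),
                          contrast = unname(z * contrast_se))),
              class = "lorentz_fit")
  })
  fits[order(vapply(fits, `[[`, 0, "center"))]
}

#' @export
print.lorentz_fit <- function(x, ...) {
  cat(sprintf("Lorentz dip: center %.2f MHz, FWHM %.2f MHz, contrast %.4f (R2 %.4f)\n",
              x$center, x$fwhm, x$contrast, x$fit_r2))
  invisible(x)
}

#' Fold-change in ODMR contrast from classifier gating
#'
#' @param raw_fit,enhanced_fit `lorentz_fit` objects for the aperture
#'   (background-diluted) and mask-gated spectra.
#' @return Enhanced contrast divided by raw contrast.
#' @export
contrast_improvement <- function(raw_fit, enhanced_fit) {
  stopifnot(inherits(raw_fit, "lorentz_fit"), inherits(enhanced_fit, "lorentz_fit"))
  if (raw_fit$contrast <= 0) stop("raw contrast is zero: fold-change undefined")
  enhanced_fit$contrast / raw_fit$contrast
}

#' Read an ODMR spectrum from a two-column CSV
#'
#' Columns: `mw_frequency_mhz`, `intensity`.
#'
#' @param path CSV path.
#' @return An [odmr_spectrum()].
#' @export
read_odmr_csv <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("mw_frequency_mhz", "intensity") %in% names(tab)))
    stop("CSV must have columns mw_frequency_mhz, intensity")
  odmr_spectrum(tab$mw_frequency_mhz, tab$intensity)
}

#' Write an ODMR spectrum to CSV
#' @param spectrum An [odmr_spectrum()].
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_odmr_csv <- function(spectrum, path) {
  utils::write.csv(data.frame(mw_frequency_mhz = spectrum$mw_frequencies,
                              intensity = spectrum$intensities),
                   path, row.names = FALSE)
  invisible(path)
}
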
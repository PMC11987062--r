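#' Remove the mean (and optionally a linear drift) from a trace
#'
#' Conditioning step before Fourier analysis of a per-pixel intensity
#' sequence.
#'
#' @param trace Numeric vector, length >= 8.
#' @param linear Also remove a least-squares linear trend?
#' @return Zero-mean trace.
#' @export
detrend <- function(trace, linear = FALSE) {
  if (length(trace) < 8) stop("trace too short (need length >= 8)")
  if (linear) {
    k <- seq_along(trace) - 1
    stats::lm.fit(cbind(1, k), trace)$residuals
  } else {
    trace - mean(trace)
  }
}

# Design matrix [1, cos(2 pi f k), sin(2 pi f k)], k = 0 .. K-1.
.sine_design <- function(K, f) {
  k <- seq_len(K) - 1
  cbind(1, cos(2 * pi * f * k), sin(2 * pi * f * k))
}

# Least-squares sine fit of every column of Y (K x N) at fixed frequency f.
# Returns amplitude, phase, offset, accuracy (R^2) vectors of length N.
# Constant or degenerate columns get amplitude 0 and accuracy 0.
.sine_fit_matrix <- function(Y, f) {
  K <- nrow(Y)
  X <- .sine_design(K, f)
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, Y))          # 3 x N
  fitted <- X %*% beta
  rss <- colSums((Y - fitted)^2)
  tss <- colSums(Y^2) - K * colMeans(Y)^2
  acc <- ifelse(tss > 0, pmax(0, pmin(1, 1 - rss / tss)), 0)
  a <- beta[2, ]; b <- beta[3, ]
  list(amplitude = sqrt(a^2 + b^2), phase = atan2(-b, a),
       offset = beta[1, ], accuracy = acc)
}

#' Periodogram peak of a detrended trace
#'
#' Discrete-Fourier periodogram over the nonzero, sub-Nyquist frequency bins
#' `j / K`; the peak location is refined by local quadratic interpolation of
#' the power around the argmax bin.
#'
#' @param trace Numeric vector (mean is removed defensively).
#' @return List with `f_hat` (cycles/frame), `peak_power_fraction` (power in
#'   the peak bin over total one-sided AC power) and `peak_bin` (integer j).
#' @export
periodogram_peak <- function(trace) {
  K <- length(trace)
  if (K < 8) stop("trace too short (need length >= 8)")
  x <- trace - mean(trace)
  p <- Mod(stats::fft(x))^2
  jmax_search <- floor((K - 1) / 2)          # strictly below Nyquist
  jmax_total <- floor(K / 2)
  total <- sum(p[1 + seq_len(jmax_total)])
  if (total <= 0) stop("zero AC power: periodogram peak undefined")
  ps <- p[1 + seq_len(jmax_search)]
  j <- which.max(ps)
  delta <- 0
  if (j > 1 && j < jmax_search) {
    pm <- ps[j - 1]; p0 <- ps[j]; pp <- ps[j + 1]
    den <- pm - 2 * p0 + pp
    if (den < 0) delta <- 0.5 * (pm - pp) / den
    delta <- max(-0.5, min(0.5, delta))
  }
  list(f_hat = (j + delta) / K, peak_power_fraction = ps[j] / total,
       peak_bin = j)
}

.sinefit_obj <- function(fit1, f) {
  structure(list(amplitude = fit1$amplitude, frequency = f,
                 phase = fit1$phase, offset = fit1$offset,
                 accuracy = fit1$accuracy),
            class = "sine_fit")
}

#' Fixed-frequency single-sine fit of a trace
#'
#' Linear least squares on the basis `{1, cos(2 pi f k), sin(2 pi f k)}`.
#' The fitted model is `offset + amplitude * cos(2 pi f k + phase)`.
#' `accuracy` is the coefficient of determination R^2 of the fit - the
#' fraction of the trace's variance explained by the single-sine model,
#' which is the "sinusoidal fitting level" used for classification. On pure
#' Gaussian white noise, accuracy follows Beta(1, (K - 3) / 2).
#'
#' @param trace Numeric vector, length >= 8.
#' @param f_mod Modulation frequency in cycles/frame, in (0, 0.5).
#' @return A `sine_fit` object: `amplitude`, `frequency` (= `f_mod`),
#'   `phase`, `offset`, `accuracy`.
#' @export
fit_sine_fixed <- function(trace, f_mod) {
  if (!is.finite(f_mod) || f_mod <= 0 || f_mod >= 0.5)
    stop("f_mod must lie in (0, 0.5) cycles/frame")
  if (length(trace) < 8) stop("trace too short (need length >= 8)")
  fit <- .sine_fit_matrix(matrix(trace, ncol = 1), f_mod)
  .sinefit_obj(lapply(fit, `[`, 1), f_mod)
}

# R^2 of the fixed-frequency fit as a function of f (for refinement).
.r2_at <- function(trace, f) .sine_fit_matrix(matrix(trace, ncol = 1), f)$accuracy

#' Free-frequency single-sine fit of a trace
#'
#' Coarse search via the periodogram peak (top bins, quadratically
#' interpolated), then bounded local maximization of the fit R^2 within one
#' bin of each candidate (tolerance 1e-6 cycles/frame). Other fields as in
#' [fit_sine_fixed()] at the selected frequency. On white noise the
#' recovered frequency is uniformly spread over the bins - the "randomly
#' spaced" frequencies of non-NV pixels.
#'
#' @param trace Numeric vector, length >= 8.
#' @param n_candidates Number of top periodogram bins refined.
#' @return A `sine_fit` object.
#' @export
fit_sine_free <- function(trace, n_candidates = 3) {
  K <- length(trace)
  if (K < 8) stop("trace too short (need length >= 8)")
  x <- detrend(trace)
  if (max(abs(x)) == 0) {
    return(structure(list(amplitude = 0, frequency = NA_real_, phase = 0,
                          offset = mean(trace), accuracy = 0),
                     class = "sine_fit"))
  }
  p <- Mod(stats::fft(x))^2
  jmax <- floor((K - 1) / 2)
  ps <- p[1 + seq_len(jmax)]
  cand <- order(ps, decreasing = TRUE)[seq_len(min(n_candidates, jmax))]
  best_f <- NA_real_; best_r2 <- -Inf
  for (j in cand) {
    lo <- max(1e-6, (j - 1) / K); hi <- min(0.5 - 1e-6, (j + 1) / K)
    opt <- stats::optimize(function(f) .r2_at(trace, f), c(lo, hi),
                           maximum = TRUE, tol = 1e-6)
    if (opt$objective > best_r2) {
      best_r2 <- opt$objective; best_f <- opt$maximum
    }
  }
  fit <- .sine_fit_matrix(matrix(trace, ncol = 1), best_f)
  .sinefit_obj(lapply(fit, `[`, 1), best_f)
}

#' Extract per-pixel feature maps from a modulation stack
#'
#' Applies [detrend()] followed by a fixed-frequency sine fit (when the
#' modulation frequency is known from the acquisition - the default and
#' recommended mode) or a free-frequency fit to every pixel trace, yielding
#' the five feature maps amplitude, frequency, phase, offset, accuracy, and
#' a global `noise_floor` scalar: 1.4826 times the median of the amplitude
#' map (MAD-about-zero convention; with sparse NV pixels the median
#' amplitude is the background's). Dead pixels (zero-variance or non-finite
#' traces) get accuracy 0 and amplitude 0.
#'
#' @param stack A [modulation_stack()].
#' @param f_mod Modulation frequency, cycles/frame; defaults to the stack
#'   metadata. Set to `NULL` with `mode = "free"` for discovery.
#' @param mode `"fixed"` or `"free"`.
#' @param detrend_linear Remove a per-pixel linear drift before fitting?
#' @return A `feature_maps` object.
#' @export
extract_features <- function(stack, f_mod = stack$meta$mod_frequency,
                             mode = c("fixed", "free"),
                             detrend_linear = FALSE) {
  stopifnot(inherits(stack, "modulation_stack"))
  mode <- match.arg(mode)
  if (mode == "fixed" && (is.null(f_mod) || is.na(f_mod)))
    stop("fixed mode requires f_mod (none supplied and none in metadata)")
  d <- dim(stack$data)
  H <- d[1]; W <- d[2]; K <- d[3]
  Y <- t(matrix(stack$data, H * W, K))       # K x N, column = pixel trace
  bad <- apply(!is.finite(Y), 2, any)
  if (any(bad)) Y[, bad] <- 0
  sdzero <- apply(Y, 2, function(y) max(y) == min(y))
  if (detrend_linear) {
    k <- seq_len(K) - 1
    Y <- stats::lm.fit(cbind(1, k), Y)$residuals
  }
  if (mode == "fixed") {
    fit <- .sine_fit_matrix(Y, f_mod)
    freq <- rep(f_mod, H * W)
  } else {
    fits <- lapply(seq_len(ncol(Y)), function(i) fit_sine_free(Y[, i]))
    fit <- list(amplitude = vapply(fits, `[[`, 0, "amplitude"),
                phase = vapply(fits, `[[`, 0, "phase"),
                offset = vapply(fits, `[[`, 0, "offset"),
                accuracy = vapply(fits, `[[`, 0, "accuracy"))
    freq <- vapply(fits, `[[`, 0, "frequency")
  }
  dead <- bad | sdzero
  fit$accuracy[dead] <- 0
  fit$amplitude[dead] <- 0
  m <- function(v) matrix(v, H, W)
  amp <- m(fit$amplitude)
  structure(list(amplitude = amp, frequency = m(freq), phase = m(fit$phase),
                 offset = m(fit$offset), accuracy = m(fit$accuracy),
                 noise_floor = 1.4826 * stats::median(amp),
                 mode = mode, f_mod = if (mode == "fixed") f_mod else NA_real_,
                 dead = m(dead)),
            class = "feature_maps")
}

#' @export
print.feature_maps <- function(x, ...) {
  cat(sprintf("feature_maps: %d x %d pixels, %s-frequency fit, noise floor %.3g\n",
              nrow(x$accuracy), ncol(x$accuracy), x$mode, x$noise_floor))
  invisible(x)
}
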
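#' Signal-to-background ratio in decibels
#'
#' `sbr_db = 20 * log10(mean(image[signal]) / max(mean(image[background]),
#' floor))` with a 1-count background floor so the metric stays finite on
#' background-free selective images. The amplitude (20 log10) convention is
#' used throughout: it places raw wide-field scenes, in which the NV
#' brightness is comparable to the background, in the ~2 dB regime.
#'
#' @param image Numeric `H x W` image (e.g. the time-mean of a stack, or a
#'   selective image).
#' @param signal_mask Logical matrix of signal pixels (nonempty).
#' @param background_mask Logical matrix of background pixels; defaults to
#'   the complement of `signal_mask`. Must be disjoint from the signal mask.
#' @param floor_counts Background floor in counts (default 1).
#' @return An `sbr_report` list: `signal_mean`, `background_mean`, `sbr_db`.
#' @export
sbr_db <- function(image, signal_mask, background_mask = NULL,
                   floor_counts = 1) {
  if (!any(signal_mask)) stop("signal mask is empty: SBR undefined")
  if (is.null(background_mask)) background_mask <- !signal_mask
  if (any(signal_mask & background_mask))
    stop("signal and background masks must be disjoint")
  s <- mean(image[signal_mask])
  b <- mean(image[background_mask])
  structure(list(signal_mean = s, background_mean = b,
                 sbr_db = 20 * log10(s / max(b, floor_counts))),
            class = "sbr_report")
}

#' @export
print.sbr_report <- function(x, ...) {
  cat(sprintf("SBR: %.2f dB (signal mean %.1f, background mean %.2f)\n",
              x$sbr_db, x$signal_mean, x$background_mean))
  invisible(x)
}

#' Sample a line profile through an image
#'
#' Bilinear interpolation at fixed steps along the segment from `start` to
#' `end` (0-based `(row, col)` pixel coordinates).
#'
#' @param image Numeric matrix.
#' @param start,end Numeric length-2 vectors `(row, col)`, 0-based.
#' @param step Sampling step in pixels (default 0.1).
#' @return A `line_profile` object with `position` (distance along the line,
#'   pixels) and `intensity`.
#' @export
line_profile <- function(image, start, end, step = 0.1) {
  len <- sqrt(sum((end - start)^2))
  if (len <= 0) stop("start and end coincide")
  t <- seq(0, 1, by = step / len)
  r <- start[1] + t * (end[1] - start[1])
  c <- start[2] + t * (end[2] - start[2])
  structure(list(position = t * len,
                 intensity = .bilinear(image, r, c),
                 start = start, end = end),
            class = "line_profile")
}

.bilinear <- function(image, r, c) {
  H <- nrow(image); W <- ncol(image)
  r <- pmin(pmax(r, 0), H - 1); c <- pmin(pmax(c, 0), W - 1)
  r0 <- pmin(floor(r), H - 2); c0 <- pmin(floor(c), W - 2)
  fr <- r - r0; fc <- c - c0
  i00 <- image[cbind(r0 + 1, c0 + 1)]
  i10 <- image[cbind(r0 + 2, c0 + 1)]
  i01 <- image[cbind(r0 + 1, c0 + 2)]
  i11 <- image[cbind(r0 + 2, c0 + 2)]
  i00 * (1 - fr) * (1 - fc) + i10 * fr * (1 - fc) +
    i01 * (1 - fr) * fc + i11 * fr * fc
}

#' Full width at half maximum of a line profile
#'
#' The half level is `min + (max - min) / 2`; the two crossings flanking the
#' unique global maximum are located by linear interpolation between
#' samples.
#'
#' @param profile A [line_profile()] object, or a numeric vector of
#'   intensities sampled at unit spacing.
#' @return Width in the profile's position units (pixels).
#' @export
fwhm <- function(profile) {
  if (inherits(profile, "line_profile")) {
    pos <- profile$position; y <- profile$intensity
  } else {
    y <- as.numeric(profile); pos <- seq_along(y) - 1
  }
  if (length(y) < 3) stop("profile too short")
  imax <- which(y == max(y))
  if (length(imax) > 1) stop("ambiguous peak: profile maximum is not unique")
  if (imax == 1L || imax == length(y))
    stop("no half-maximum crossing on one side of the peak")
  half <- min(y) + (max(y) - min(y)) / 2
  cross <- function(side_idx) {
    # last crossing of the half level walking away from the peak
    for (i in side_idx) {
      j <- i + sign(imax - i)   # neighbor toward the peak
      if (y[i] <= half && y[j] > half) {
        t <- (half - y[i]) / (y[j] - y[i])
        return(pos[i] + t * (pos[j] - pos[i]))
      }
    }
    stop("no half-maximum crossing on one side of the peak")
  }
  left <- cross(rev(seq_len(imax - 1)))
  right <- cross((imax + 1):length(y))
  abs(right - left)
}

#' Pixelwise classification metrics against ground truth
#'
#' @param mask Logical matrix (prediction).
#' @param truth_mask Logical matrix (ground truth), same shape.
#' @return List with confusion counts `tp`, `fp`, `fn`, `tn`, and
#'   `precision`, `recall`, `f1` (NaN where undefined).
#' @export
classification_metrics <- function(mask, truth_mask) {
  if (!all(dim(mask) == dim(truth_mask))) stop("mask shapes do not match")
  tp <- sum(mask & truth_mask)
  fp <- sum(mask & !truth_mask)
  fn <- sum(!mask & truth_mask)
  tn <- sum(!mask & !truth_mask)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NaN
  recall <- if (tp + fn > 0) tp / (tp + fn) else NaN
  f1 <- if (is.finite(precision) && is.finite(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NaN
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       precision = precision, recall = recall, f1 = f1)
}
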
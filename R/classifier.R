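#' Classifier thresholds
#'
#' The decision rule is a strict conjunction of physically interpretable
#' criteria: a pixel is NV iff its single-sine fitting accuracy reaches
#' `accuracy_min`, its fitted amplitude reaches `amplitude_min_sigma` times
#' the robust amplitude noise floor, and (free-frequency mode only) its
#' fitted frequency lies within `freq_tol` of the acquisition modulation
#' frequency.
#'
#' @param accuracy_min Minimum fitting accuracy (R^2), in (0, 1).
#' @param amplitude_min_sigma Minimum amplitude in multiples of the
#'   feature-map noise floor (> 0).
#' @param freq_tol Frequency tolerance, cycles/frame (>= 0; free mode only).
#' @return An object of class `classifier_thresholds`.
#' @export
classifier_thresholds <- function(accuracy_min = 0.8, amplitude_min_sigma = 5,
                                  freq_tol = 0.02) {
  if (!is.finite(accuracy_min) || accuracy_min <= 0 || accuracy_min >= 1)
    stop("accuracy_min must lie in (0, 1)")
  if (!is.finite(amplitude_min_sigma) || amplitude_min_sigma <= 0)
    stop("amplitude_min_sigma must be > 0")
  if (!is.finite(freq_tol) || freq_tol < 0) stop("freq_tol must be >= 0")
  structure(list(accuracy_min = accuracy_min,
                 amplitude_min_sigma = amplitude_min_sigma,
                 freq_tol = freq_tol),
            class = "classifier_thresholds")
}

#' Classify pixels into NV and non-NV
#'
#' Applies the threshold conjunction to the feature maps. No spatial
#' post-processing is applied by default; set `min_cluster` > 1 to drop
#' 4-connected components smaller than that size.
#'
#' @param features A `feature_maps` object from [extract_features()].
#' @param thresholds A [classifier_thresholds()].
#' @param f_mod Modulation frequency for the frequency criterion; only used
#'   when the features came from a free-frequency fit.
#' @param min_cluster Minimum connected-component size kept (default 1:
#'   single-pixel NV detections are meaningful at this sparsity).
#' @return Logical `H x W` matrix (class `nv_mask`) with attribute `n_pixels`.
#' @export
classify_pixels <- function(features, thresholds = classifier_thresholds(),
                            f_mod = NULL, min_cluster = 1L) {
  stopifnot(inherits(features, "feature_maps"),
            inherits(thresholds, "classifier_thresholds"))
  mask <- features$accuracy >= thresholds$accuracy_min &
    features$amplitude >= thresholds$amplitude_min_sigma * features$noise_floor
  if (identical(features$mode, "free")) {
    if (is.null(f_mod)) f_mod <- features$f_mod
    if (!is.null(f_mod) && !is.na(f_mod))
      mask <- mask & !is.na(features$frequency) &
        abs(features$frequency - f_mod) <= thresholds$freq_tol
  }
  if (min_cluster > 1L) mask <- .drop_small_components(mask, min_cluster)
  structure(mask, n_pixels = sum(mask), class = c("nv_mask", class(mask)))
}

# 4-connected component labelling by flood fill (masks are sparse, so a
# simple stack-based fill is plenty).
.drop_small_components <- function(mask, min_size) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  idx <- which(mask)
  H <- nrow(mask)
  for (s in idx) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    comp <- integer(0)
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[p] != 0L) next
      lab[p] <- cur
      comp <- c(comp, p)
      r <- (p - 1L) %% H + 1L; cc <- (p - 1L) %/% H + 1L
      for (q in c(if (r > 1L) p - 1L, if (r < H) p + 1L,
                  if (cc > 1L) p - H, if (cc < ncol(mask)) p + H)) {
        if (mask[q] && lab[q] == 0L) stack <- c(stack, q)
      }
    }
    if (length(comp) < min_size) mask[comp] <- FALSE
  }
  mask
}

#' Background-suppressed selective image
#'
#' NV pixels carry their across-frame mean intensity (`mode = "mean"`) or
#' their fitted modulation amplitude (`mode = "amplitude"`, a background-free
#' brightness estimate); all non-NV pixels are exactly zero.
#'
#' @param stack A [modulation_stack()].
#' @param mask Logical matrix from [classify_pixels()] (or ground truth).
#' @param mode `"mean"` or `"amplitude"`.
#' @param features Required for `mode = "amplitude"`: the `feature_maps`
#'   holding the fitted amplitudes.
#' @return Numeric `H x W` image.
#' @export
selective_image <- function(stack, mask, mode = c("mean", "amplitude"),
                            features = NULL) {
  stopifnot(inherits(stack, "modulation_stack"))
  mode <- match.arg(mode)
  d <- dim(stack$data)
  if (!all(dim(mask) == d[1:2])) stop("mask shape does not match the stack")
  img <- matrix(0, d[1], d[2])
  if (mode == "mean") {
    mean_img <- rowMeans(stack$data, dims = 2)
    img[mask] <- mean_img[mask]
  } else {
    if (is.null(features)) stop("mode = \"amplitude\" requires feature maps")
    img[mask] <- features$amplitude[mask]
  }
  img
}
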
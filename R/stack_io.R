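#' Modulation stack container
#'
#' An `H x W x K` tensor of nonnegative camera counts together with the
#' per-frame polarization angles and acquisition metadata. Frame `k`
#' (1-based in R) corresponds to angle `angles[k]`; angles must be strictly
#' increasing and equidistant to within 1e-6 rad.
#'
#' @param data Numeric `H x W x K` array, finite and >= 0.
#' @param angles Numeric vector of `K` polarization angles, radians.
#' @param meta List of acquisition metadata; `mod_frequency` (cycles/frame)
#'   is used as the default fitting frequency downstream.
#' @return An object of class `modulation_stack`.
#' @export
modulation_stack <- function(data, angles, meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be an H x W x K array")
  K <- dim(data)[3]
  if (length(angles) != K) stop("length(angles) must equal the frame count K")
  if (K >= 2) {
    d <- diff(angles)
    if (any(d <= 0)) stop("polarization angles must be strictly increasing")
    if (max(d) - min(d) > 1e-6)
      stop("polarization angles must be equidistant within 1e-6 rad")
  }
  if (!all(is.finite(data))) stop("stack intensities must be finite")
  if (min(data) < 0) stop("stack intensities must be >= 0")
  structure(list(data = data, angles = as.numeric(angles), meta = meta),
            class = "modulation_stack")
}

#' @export
dim.modulation_stack <- function(x) dim(x$data)

#' @export
print.modulation_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("modulation_stack: %d x %d pixels, %d frames, f = %s cycles/frame\n",
              d[1], d[2], d[3],
              format(x$meta$mod_frequency %||% NA)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a modulation stack as a multi-page 16-bit TIFF with JSON sidecar
#'
#' Values are clipped to `[0, 65535]` (the number of clipped samples is
#' reported in a warning and returned as an attribute) and rounded to
#' integer counts. The sidecar records the angle list and acquisition
#' metadata.
#'
#' @param stack A [modulation_stack()].
#' @param path Output TIFF path; the sidecar goes to the same path with a
#'   `.json` extension.
#' @return Invisibly, `path`, with attribute `clipped` = number of samples
#'   clipped to the 16-bit range.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "modulation_stack"))
  d <- stack$data
  n_clip <- sum(d > 65535)
  if (n_clip > 0) {
    warning(sprintf("%d sample(s) clipped to the 16-bit range", n_clip))
    d[d > 65535] <- 65535
  }
  d[d < 0] <- 0
  K <- dim(d)[3]
  pages <- lapply(seq_len(K), function(k) round(d[, , k]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(
    list(angles = stack$angles,
         mod_frequency = stack$meta$mod_frequency %||% NA,
         n_frames = K, meta = stack$meta),
    .sidecar_path(path), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(structure(path, clipped = n_clip))
}

#' Read a modulation stack from a multi-page TIFF
#'
#' Page order is frame order. Angles and metadata come from the JSON sidecar
#' written by [write_stack()]; for sidecar-less files supply `angles` (and
#' optionally `mod_frequency`) directly.
#'
#' @param path TIFF path.
#' @param angles Optional angle vector overriding/replacing the sidecar.
#' @param mod_frequency Optional modulation frequency, cycles/frame.
#' @return A [modulation_stack()].
#' @export
read_stack <- function(path, angles = NULL, mod_frequency = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  K <- length(pages)
  meta <- list()
  side <- .sidecar_path(path)
  if (is.null(angles)) {
    if (!file.exists(side))
      stop("no JSON sidecar found and no angles supplied")
    sc <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (length(sc$angles) != K)
      stop(sprintf("sidecar angle count (%d) does not match TIFF page count (%d)",
                   length(sc$angles), K))
    angles <- sc$angles
    meta <- as.list(sc$meta)
    if (is.null(mod_frequency)) mod_frequency <- sc$mod_frequency
  } else if (length(angles) != K) {
    stop(sprintf("supplied angle count (%d) does not match TIFF page count (%d)",
                 length(angles), K))
  }
  if (!is.null(mod_frequency) && !is.na(mod_frequency))
    meta$mod_frequency <- mod_frequency
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  data <- array(0, dim = c(H, W, K))
  for (k in seq_len(K)) data[, , k] <- pages[[k]]
  modulation_stack(data, angles, meta)
}

# Scaled 32-bit float TIFF: the R tiff backend stores samples in [0, 1], so
# each map is written as (x - offset) / scale with the affine transform in a
# JSON sidecar; round trips are exact to float32 precision.
.write_float_tiff <- function(m, path) {
  off <- min(m); sc <- max(m) - off
  if (sc <= 0) sc <- 1
  tiff::writeTIFF((m - off) / sc, path, bits.per.sample = 32L,
                  compression = "none")
  jsonlite::write_json(list(offset = off, scale = sc), .sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.read_float_tiff <- function(path) {
  sc <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  tiff::readTIFF(path) * sc$scale + sc$offset
}

#' Write per-pixel feature maps
#'
#' One 32-bit float TIFF per feature (amplitude, frequency, phase, offset,
#' accuracy) plus a summary CSV of per-pixel features. With a mask, the CSV
#' holds only the masked pixels.
#'
#' @param features A `feature_maps` object from [extract_features()].
#' @param dir Output directory (created if missing).
#' @param mask Optional logical matrix restricting the CSV export.
#' @return Invisibly, the named vector of paths written.
#' @export
write_feature_maps <- function(features, dir, mask = NULL) {
  stopifnot(inherits(features, "feature_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nm <- c("amplitude", "frequency", "phase", "offset", "accuracy")
  paths <- character(0)
  for (f in nm) {
    p <- file.path(dir, paste0(f, ".tif"))
    .write_float_tiff(features[[f]], p)
    paths[f] <- p
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(features$accuracy),
                                    ncol(features$accuracy))
  idx <- which(mask, arr.ind = TRUE)
  tab <- data.frame(row = idx[, 1] - 1L, col = idx[, 2] - 1L,
                    amplitude = features$amplitude[mask],
                    frequency = features$frequency[mask],
                    phase = features$phase[mask],
                    offset = features$offset[mask],
                    accuracy = features$accuracy[mask])
  csv <- file.path(dir, "features.csv")
  utils::write.csv(tab, csv, row.names = FALSE)
  paths["csv"] <- csv
  jsonlite::write_json(list(noise_floor = features$noise_floor,
                            mode = features$mode),
                       file.path(dir, "feature_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read feature maps written by [write_feature_maps()]
#'
#' @param dir Directory holding the feature TIFFs.
#' @return A `feature_maps` object.
#' @export
read_feature_maps <- function(dir) {
  nm <- c("amplitude", "frequency", "phase", "offset", "accuracy")
  maps <- lapply(nm, function(f) .read_float_tiff(file.path(dir, paste0(f, ".tif"))))
  names(maps) <- nm
  meta <- jsonlite::read_json(file.path(dir, "feature_meta.json"),
                              simplifyVector = TRUE)
  structure(c(maps, list(noise_floor = meta$noise_floor, mode = meta$mode)),
            class = "feature_maps")
}

#' Write a boolean mask as an 8-bit TIFF (255 = NV)
#'
#' @param mask Logical matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF((mask * 1) * 255 / 255, path, bits.per.sample = 8L,
                  compression = "none")
  invisible(path)
}

#' Read a mask written by [write_mask()]
#' @param path TIFF path.
#' @return Logical matrix.
#' @export
read_mask <- function(path) {
  tiff::readTIFF(path, as.is = TRUE) > 0
}

#' Read a scene description from a JSON config file
#'
#' Top-level keys (exactly): `height`, `width`, `emitters` (array of objects
#' with `row`, `col`, `alpha`, `theta`, `base_intensity`), `background`
#' (fields of [background_spec()]), `acquisition` (fields of
#' [acquisition_config()]). Optional `mask_rel_cutoff`.
#'
#' @param path JSON path.
#' @return A [synthetic_scene()].
#' @export
read_scene_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("height", "width", "emitters", "background", "acquisition")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("config is missing keys: ", paste(miss, collapse = ", "))
  emitters <- lapply(seq_len(NROW(cfg$emitters)), function(i) {
    e <- cfg$emitters[i, , drop = FALSE]
    nv_emitter(e$row, e$col, e$alpha, e$theta, e$base_intensity)
  })
  bg <- do.call(background_spec, as.list(cfg$background))
  acq <- do.call(acquisition_config, as.list(cfg$acquisition))
  synthetic_scene(cfg$height, cfg$width, emitters, bg, acq,
                  mask_rel_cutoff = cfg$mask_rel_cutoff %||% 0.1)
}
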
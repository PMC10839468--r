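# Readers and writers for the standard formats touched: PNG (8/16-bit
# grayscale) and NIfTI volumes processed slice-wise, plus the flat YAML
# run configuration. Coordinate convention: row-major (row, column);
# the NIfTI slice axis is the third axis.

#' Read an image file into an ImageGrid
#'
#' PNG files are returned on their storage scale (0..255 for 8-bit,
#' 0..65535 for 16-bit). NIfTI volumes require a slice index and are by
#' default min-max scaled per volume to 0..255 (the scaling is recorded
#' in the \code{"scaling"} attribute).
#'
#' @param path file path (.png, .nii or .nii.gz).
#' @param slice 1-based slice index along the third axis (NIfTI only).
#' @param toGray collapse RGB PNG to luminance instead of erroring.
#' @param normalize min-max scale NIfTI data to 0..255 (default TRUE).
#' @return An \code{\linkS4class{ImageGrid}}.
#' @export
readImageGrid <- function(path, slice = NULL, toGray = FALSE,
                          normalize = TRUE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lower <- tolower(path)
  if (grepl("\\.png$", lower)) {
    a <- png::readPNG(path, info = TRUE)
    info <- attr(a, "info")
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    peak <- 2^depth - 1
    if (length(dim(a)) == 3L) {
      if (!toGray)
        stop("RGB PNG: pass toGray = TRUE to collapse to luminance")
      a <- 0.2989 * a[, , 1L] + 0.587 * a[, , 2L] + 0.114 * a[, , 3L]
    }
    img <- ImageGrid(a * peak, valueRange = c(0, peak))
    attr(img@pixels, "bitDepth") <- depth
    return(img)
  }
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    vol <- RNifti::readNifti(path)
    d <- dim(vol)
    if (length(d) >= 3L && d[3L] > 1L) {
      if (is.null(slice))
        stop(sprintf("volume has %d slices: a slice index is required",
                     d[3L]))
      if (slice < 1L || slice > d[3L])
        stop(sprintf("slice %d out of range 1..%d", slice, d[3L]))
      m <- vol[, , slice]
    } else {
      m <- if (length(d) >= 3L) vol[, , 1L] else vol[, ]
    }
    m <- matrix(as.numeric(m), nrow(m), ncol(m))
    scaling <- c(low = min(m), high = max(m))
    if (normalize) {
      rngv <- max(m) - min(m)
      m <- if (rngv > 0) (m - min(m)) / rngv * 255 else m * 0
    }
    img <- ImageGrid(m, valueRange = c(0, 255))
    attr(img@pixels, "scaling") <- scaling
    return(img)
  }
  stop(sprintf("unknown image format: %s", path))
}

#' Write an ImageGrid to disk
#'
#' PNG output clips to the storage range, rescales to 8 bits and rounds
#' (clip-then-round); values outside the declared range trigger a warning
#' before clipping. NIfTI output stores the raw floating-point slice and
#' is the route for higher-depth data (the PNG writer is 8-bit only;
#' 16-bit PNG is supported on the read side).
#'
#' @param img an \code{\linkS4class{ImageGrid}} (storage scale).
#' @param path output path (.png, .nii or .nii.gz).
#' @param bitDepth PNG bit depth; only 8 is supported for writing.
#' @export
writeImageGrid <- function(img, path, bitDepth = 8L) {
  if (bitDepth != 8L && grepl("\\.png$", tolower(path)))
    stop("the PNG writer is 8-bit only; write NIfTI for higher depths")
  stopifnot(is(img, "ImageGrid"))
  if (img@modelScale) img <- toStorageScale(img)
  m <- img@pixels
  vr <- img@valueRange
  lower <- tolower(path)
  if (grepl("\\.png$", lower)) {
    if (any(m < vr[1L]) || any(m > vr[2L]))
      warning("values outside the declared range were clipped on write")
    m <- pmin(pmax(m, vr[1L]), vr[2L])
    u <- (m - vr[1L]) / diff(vr)
    peak <- 2^bitDepth - 1
    u <- round(u * peak) / peak
    png::writePNG(u, target = path, dpi = NULL)
    return(invisible(path))
  }
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    RNifti::writeNifti(RNifti::asNifti(array(m, dim = c(dim(m), 1L))), path)
    return(invisible(path))
  }
  stop(sprintf("unknown image format: %s", path))
}

# Flat run configuration with strict key checking. Unknown keys are the
# classic silent failure mode for hyper-parameters, so they are rejected.
defaultRunConfig <- function() {
  list(scheduleKind = "linear-gamma", scheduleT = 5000L,
       gammaStart = 1 - 1e-4, gammaEnd = 5e-4,
       baseChannels = 64L, depthMultipliers = c(1L, 2L, 4L, 8L, 16L),
       embDim = 16L, embHidden = 32L,
       epochs = 10L, batchSize = 8L, learningRate = 1e-4, clip = 1.0,
       hrShape = c(256L, 256L), lrShape = c(86L, 128L),
       patchSize = 7L, stride = 3L, maxAttempts = 10L,
       seed = 1L, outDir = ".")
}

#' Read / write the run configuration
#'
#' A flat YAML document of hyper-parameters; keys missing from the file
#' keep their defaults, unknown keys are an error.
#'
#' @param path YAML file path.
#' @param config named list (subset of the default keys).
#' @return \code{readRunConfig} returns the merged config list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path))
  user <- yaml::read_yaml(path)
  base <- defaultRunConfig()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  base[names(user)] <- user
  base
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  base <- defaultRunConfig()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  full <- base
  full[names(config)] <- config
  yaml::write_yaml(full, path)
  invisible(path)
}
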
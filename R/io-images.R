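# TIFF image series with JSON calibration sidecars, and ImageJ rectangle
# .roi files. Coordinate conventions: images are (row, col) with origin
# top-left; ROIs are c(x, y, w, h) in pixels, 0-based, half-open on the
# right/bottom; physical x = col * pixelSize.

sidecarPath <- function(path) sub("\\.tiff?$", ".json", path,
                                  ignore.case = TRUE)

#' Load a TIFF stack as an ImageSeries
#'
#' Reads a single-channel multi-page TIFF. Calibration (pixel size, frame
#' interval, intensity scale) is taken from a JSON sidecar written by
#' [writeImageSeries()] when present; explicit arguments override the
#' sidecar (a message is emitted on conflict). Missing calibration with no
#' override is an error. Interleaved multi-channel TIFFs are rejected with
#' a pointer to per-channel files; 8-, 16- and 32-bit stacks all load to
#' the same float intensities up to quantization.
#'
#' @param path TIFF file.
#' @param pixelSize um/px override.
#' @param frameInterval s override.
#' @param channelLabel optional label.
#' @return An [ImageSeries-class].
#' @export
loadImageSeries <- function(path, pixelSize = NULL, frameInterval = NULL,
                            channelLabel = "") {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(dim(pages[[1]])) == 3L) {
    stop("multi-channel interleaved TIFF not supported: ",
         "save each channel as its own single-channel stack")
  }
  meta <- list()
  sc <- sidecarPath(path)
  if (file.exists(sc)) meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  pick <- function(arg, key, what) {
    fromFile <- meta[[key]]
    if (!is.null(arg)) {
      if (!is.null(fromFile) && abs(arg - fromFile) > 1e-12) {
        message(sprintf("%s: argument (%g) overrides sidecar (%g)",
                        what, arg, fromFile))
      }
      arg
    } else if (!is.null(fromFile)) {
      fromFile
    } else {
      stop(sprintf("missing calibration: provide %s (no sidecar found)",
                   what))
    }
  }
  px <- pick(pixelSize, "pixel_size_um", "pixelSize")
  fi <- pick(frameInterval, "frame_interval_s", "frameInterval")
  scale <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else 1
  arr <- array(unlist(pages, use.names = FALSE),
               dim = c(dim(pages[[1]]), length(pages))) * scale
  lbl <- if (nzchar(channelLabel)) channelLabel else
    if (!is.null(meta$channel_label)) meta$channel_label else ""
  ImageSeries(arr, px, fi, lbl)
}

#' Write an ImageSeries as a TIFF stack with a JSON sidecar
#'
#' Intensities are scaled into \[0, 1\] and stored as 32-bit float samples;
#' the scale factor, pixel size, frame interval and channel label go into
#' `<path>.json` so that [loadImageSeries()] restores physical intensities.
#'
#' @param series An [ImageSeries-class].
#' @param path output TIFF path.
#' @return Invisibly, the sidecar path.
#' @export
writeImageSeries <- function(series, path) {
  stopifnot(is(series, "ImageSeries"))
  f <- frames(series)
  mx <- max(f)
  scale <- if (mx > 0) mx else 1
  pages <- lapply(seq_len(dim(f)[3]), function(i) f[, , i] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  sc <- sidecarPath(path)
  jsonlite::write_json(list(pixel_size_um = pixelSize(series),
                            frame_interval_s = frameInterval(series),
                            intensity_scale = scale,
                            channel_label = channelLabel(series)),
                       sc, auto_unbox = TRUE, digits = NA)
  invisible(sc)
}

# ImageJ .roi type codes (byte 6 of the header).
ijRoiTypes <- c("polygon", "rect", "oval", "line", "freeline", "polyline",
                "noRoi", "freehand", "traced", "angle", "point")

#' Read an ImageJ rectangle ROI file
#'
#' Parses the binary ImageJ `.roi` format and returns the rectangle as
#' c(x, y, w, h) in pixels, origin top-left, 0-based, half-open on the
#' right/bottom. Only rectangle ROIs are supported; other types raise an
#' error naming the type.
#'
#' @param path `.roi` file.
#' @return Integer vector c(x, y, w, h).
#' @export
readImagejRoi <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 16L || rawToChar(raw[1:4]) != "Iout") {
    stop("not an ImageJ .roi file: ", path)
  }
  type <- as.integer(raw[7]) + 1L
  typeName <- if (type <= length(ijRoiTypes)) ijRoiTypes[type] else "unknown"
  if (typeName != "rect") {
    stop(sprintf("unsupported ROI type '%s': only rectangles are supported",
                 typeName))
  }
  getShort <- function(off) {
    readBin(raw[(off + 1):(off + 2)], "integer", size = 2, endian = "big")
  }
  top <- getShort(8); left <- getShort(10)
  bottom <- getShort(12); right <- getShort(14)
  c(x = left, y = top, w = right - left, h = bottom - top)
}

#' Write an ImageJ rectangle ROI file
#'
#' Minimal conforming writer (header version 226, rectangle type) for
#' round-tripping bleach-region annotations.
#'
#' @param roi c(x, y, w, h) in pixels.
#' @param path output `.roi` path.
#' @return Invisibly, `path`.
#' @export
writeImagejRoi <- function(roi, path) {
  roi <- as.integer(roi)
  stopifnot(length(roi) == 4L, all(roi[3:4] > 0L))
  buf <- raw(64)
  buf[1:4] <- charToRaw("Iout")
  putShort <- function(buf, off, val) {
    buf[(off + 1):(off + 2)] <- writeBin(as.integer(val), raw(), size = 2,
                                         endian = "big")
    buf
  }
  buf <- putShort(buf, 4, 226L)      # version
  buf[7] <- as.raw(1L)               # type: rect
  buf <- putShort(buf, 8, roi[2])              # top
  buf <- putShort(buf, 10, roi[1])             # left
  buf <- putShort(buf, 12, roi[2] + roi[4])    # bottom
  buf <- putShort(buf, 14, roi[1] + roi[3])    # right
  writeBin(buf, path)
  invisible(path)
}
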
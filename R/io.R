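# Raster input/output and configuration files.
#
# Phase and intensity rasters are exchanged as float32 TIFF (radians /
# intensity as-is); 8/16-bit TIFF and PNG inputs are accepted and
# rescaled to [0, 1] with the quantisation scale recorded. Writing goes
# through a minimal uncompressed float32 TIFF encoder, because the
# general-purpose TIFF writer available to R clamps floating-point
# samples into [0, 1], which would corrupt radian-valued phase maps.

write_float_tiff <- function(x, path) {
  stopifnot(is.matrix(x), is.numeric(x))
  nr <- nrow(x); nc <- ncol(x)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)                       # little-endian
  writeBin(as.integer(42), con, size = 2, endian = "little")
  writeBin(as.integer(8), con, size = 4, endian = "little")  # IFD offset
  tags <- list(
    c(256L, 3L, 1L, nc),        # ImageWidth
    c(257L, 3L, 1L, nr),        # ImageLength
    c(258L, 3L, 1L, 32L),       # BitsPerSample
    c(259L, 3L, 1L, 1L),        # Compression: none
    c(262L, 3L, 1L, 1L),        # Photometric: BlackIsZero
    c(273L, 4L, 1L, 0L),        # StripOffsets (patched below)
    c(277L, 3L, 1L, 1L),        # SamplesPerPixel
    c(278L, 3L, 1L, nr),        # RowsPerStrip
    c(279L, 4L, 1L, 4L * nr * nc),  # StripByteCounts
    c(339L, 3L, 1L, 3L))        # SampleFormat: IEEE float
  n_tags <- length(tags)
  data_offset <- 8 + 2 + n_tags * 12 + 4
  tags[[6]][4] <- data_offset
  writeBin(as.integer(n_tags), con, size = 2, endian = "little")
  for (tg in tags) {
    writeBin(as.integer(tg[1]), con, size = 2, endian = "little")
    writeBin(as.integer(tg[2]), con, size = 2, endian = "little")
    writeBin(as.integer(tg[3]), con, size = 4, endian = "little")
    if (tg[2] == 3L) {          # SHORT payload, left-justified
      writeBin(as.integer(tg[4]), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(tg[4]), con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little")       # no next IFD
  # TIFF stores rows contiguously: transpose the column-major matrix
  writeBin(as.numeric(t(x)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a raster image
#'
#' Reads TIFF (including float32) or PNG into a numeric matrix.
#' Floating-point TIFF values are returned as stored; integer inputs are
#' rescaled to `[0, 1]` and the quantisation scale (grey levels per
#' unit) is recorded in the `scale` attribute. Multi-channel images are
#' reduced to luminance with a warning.
#'
#' @param path file path, `.tif`/`.tiff` or `.png`.
#' @return numeric matrix with attributes `scale` (or `NA` for float
#'   data) and `format`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path, info = TRUE)
    fmt <- "TIFF"
  } else if (ext == "png") {
    x <- png::readPNG(path)
    fmt <- "PNG"
  } else stop("unsupported raster format: .", ext)
  if (length(dim(x)) == 3) {
    warning("multi-channel image converted to luminance")
    x <- 0.2126 * x[, , 1] + 0.7152 * x[, , 2] + 0.0722 * x[, , 3]
  }
  info <- attr(x, "info")
  bps <- if (!is.null(info$bits.per.sample)) info$bits.per.sample[1] else NULL
  fmt_code <- if (!is.null(info$sample.format)) info$sample.format[1] else NULL
  is_float <- identical(fmt_code, "float") ||
    (fmt == "TIFF" && !is.null(bps) && bps == 32)
  scale <- if (fmt == "PNG") 255 else if (is_float) NA_real_
  else if (!is.null(bps)) 2^bps - 1 else NA_real_
  out <- matrix(as.numeric(x), nrow(x), ncol(x))
  attr(out, "scale") <- scale
  attr(out, "format") <- fmt
  out
}

#' Write a raster image
#'
#' Float32 TIFF by default (lossless for radian phase maps up to float32
#' precision). Integer export must be requested explicitly through
#' `quantize`, which maps the value range onto the grey levels of the
#' chosen bit depth.
#'
#' @param x numeric matrix.
#' @param path output path; `.tif`/`.tiff` for float32 (default) or, with
#'   `quantize`, `.png`/`.tif` integer output.
#' @param quantize `NULL` (float32 TIFF) or bit depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path, quantize = NULL) {
  stopifnot_matrix(x)
  ext <- tolower(tools::file_ext(path))
  if (is.null(quantize)) {
    if (!ext %in% c("tif", "tiff"))
      stop("float rasters are stored as .tif; pass quantize= for integer formats")
    return(invisible(write_float_tiff(x, path)))
  }
  if (!quantize %in% c(8, 16)) stop("quantize must be 8 or 16")
  lo <- min(x); hi <- max(x)
  y <- if (hi > lo) (x - lo) / (hi - lo) else x * 0
  if (ext == "png") png::writePNG(y, path)
  else tiff::writeTIFF(y, path, bits.per.sample = quantize)
  invisible(path)
}

config_defaults <- function() {
  list(mu = 100, tau = 0.25, tol = 1e-3, max_iters = 2000,
       denoiser = "wavelet", w_min = 3, w_max = 13, w_step = 2,
       n_modes = 3, direction_mode = "estimated",
       aberration_correct = FALSE, seed = NULL)
}

#' Load a pipeline configuration file
#'
#' Reads a YAML (or JSON) configuration into a [vhqpi_config()]. Omitted
#' keys take the method defaults (`mu = 100`, `tau = 0.25`, window sweep
#' 3..13); unknown keys and out-of-range values are rejected with the
#' offending key named.
#'
#' @param path YAML/JSON file; an empty file yields the full defaults.
#' @return a `vhqpi_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defs <- config_defaults()
  unknown <- setdiff(names(raw), names(defs))
  if (length(unknown))
    stop("unknown configuration key: ", paste(unknown, collapse = ", "))
  merged <- utils::modifyList(defs, raw)
  do.call(vhqpi_config, merged)
}
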
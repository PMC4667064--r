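img_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") return("png")
  if (ext %in% c("tif", "tiff")) return("tiff")
  stop(sprintf("unsupported image format '.%s' (use PNG or TIFF): %s",
               ext, path), call. = FALSE)
}

# Collapse a H x W x C array to a single channel. Channels must be
# identical (an alpha channel, if present, must be fully opaque); there is
# no silent luminance conversion.
collapse_channels <- function(a, path) {
  if (length(dim(a)) == 2L) return(a)
  if (length(dim(a)) != 3L)
    stop(sprintf("unexpected image dimensions in %s", path), call. = FALSE)
  nc <- dim(a)[3L]
  if (nc %in% c(2L, 4L)) {  # gray+alpha / RGBA
    alpha <- a[, , nc]
    if (any(alpha != 1))
      stop(sprintf("%s has a non-trivial alpha channel", path), call. = FALSE)
    a <- a[, , -nc, drop = FALSE]
    nc <- dim(a)[3L]
  }
  first <- a[, , 1L]
  for (c in seq_len(nc)[-1L])
    if (any(a[, , c] != first))
      stop(sprintf(paste0("%s is multi-channel with non-identical channels; ",
                          "convert to grayscale explicitly"), path),
           call. = FALSE)
  first
}

#' Read a grayscale PNG or TIFF image
#'
#' Reads an 8- or 16-bit single-channel raster (multi-channel files are
#' accepted only when all channels are identical and any alpha channel is
#' fully opaque) and normalizes intensities to \[0, 1\]. The original bit
#' depth is recorded in the `bit_depth` attribute so [write_gray()] can
#' round-trip losslessly.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return numeric matrix in \[0, 1\] with attribute `bit_depth` (8 or 16).
#' @export
read_gray <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  fmt <- img_format(path)
  if (fmt == "png") {
    a <- png::readPNG(path, info = TRUE)
    info <- attr(a, "info")
    depth <- if (!is.null(info$bit.depth)) as.integer(info$bit.depth) else 8L
  } else {
    a <- tiff::readTIFF(path, info = TRUE)
    depth <- attr(a, "bits.per.sample")
    depth <- if (is.null(depth)) 8L else as.integer(depth[1L])
  }
  img <- collapse_channels(unclass(a), path)
  attributes(img) <- list(dim = dim(img))
  attr(img, "bit_depth") <- depth
  img
}

#' Write a grayscale image to PNG or TIFF
#'
#' Inverse of the [read_gray()] normalization: intensities in \[0, 1\] are
#' quantized back to the requested bit depth, losslessly for values that
#' originated from a raster of that depth. Out-of-range values are clipped
#' with a warning. PNG output is 8-bit; 16-bit output uses TIFF.
#'
#' @param image numeric matrix with values in \[0, 1\].
#' @param path output path (`.png`, `.tif`, `.tiff`).
#' @param bit_depth 8 or 16; defaults to the image's `bit_depth` attribute,
#'   or 8.
#' @return the path, invisibly.
#' @export
write_gray <- function(image, path, bit_depth = NULL) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (is.null(bit_depth))
    bit_depth <- if (!is.null(attr(image, "bit_depth")))
      attr(image, "bit_depth") else 8L
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L))
    stop("`bit_depth` must be 8 or 16", call. = FALSE)
  if (min(image) < 0 || max(image) > 1) {
    warning(sprintf("clipping %d out-of-range pixel(s) to [0, 1]",
                    sum(image < 0 | image > 1)))
    image <- pmin(pmax(image, 0), 1)
  }
  fmt <- img_format(path)
  img <- matrix(as.numeric(image), nrow(image), ncol(image))
  if (fmt == "png") {
    if (bit_depth != 8L)
      stop("PNG output is 8-bit; use TIFF for 16-bit output", call. = FALSE)
    png::writePNG(img, path)
  } else {
    tiff::writeTIFF(img, path, bits.per.sample = bit_depth,
                    compression = "none")
  }
  invisible(path)
}

# Dump an intermediate map as a 16-bit TIFF rescaled to the full range, with
# the affine scale recorded in a sidecar text file so values are recoverable.
dump_map <- function(map, path) {
  lo <- min(map); hi <- max(map)
  scaled <- if (hi > lo) (map - lo) / (hi - lo) else map * 0
  write_gray(scaled, path, bit_depth = 16L)
  writeLines(c(sprintf("min=%.17g", lo), sprintf("max=%.17g", hi),
               "encoding=value = min + pixel * (max - min)"),
             paste0(path, ".scale.txt"))
  invisible(path)
}
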
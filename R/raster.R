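#' Raster image container
#'
#' A thin container for 8-bit grayscale raster images with a known physical
#' scale. The pixel grid uses the image-processing convention: origin at the
#' top-left, x to the right (columns), y downward (rows). The centre of pixel
#' `(r, c)` sits at world coordinates `origin + (c - 0.5, r - 0.5) / scale`
#' (millimetres).
#'
#' @param pixels numeric matrix of intensities in `[0, 255]`; rows are y,
#'   columns are x.
#' @param scale pixels per millimetre (> 0).
#' @param origin numeric length-2, world (mm) coordinates of the image's
#'   top-left corner.
#' @param meta optional list of provenance / ground-truth metadata.
#' @return An object of class `raster_image`.
#' @export
raster_image <- function(pixels, scale, origin = c(0, 0), meta = list()) {
  stop_if(!is.matrix(pixels) || !is.numeric(pixels) || any(dim(pixels) < 1L),
          "'pixels' must be a non-empty numeric matrix")
  assert_scalar_pos(scale, "scale")
  stop_if(min(pixels) < 0 || max(pixels) > 255, "'pixels' must lie in [0, 255]")
  structure(list(pixels = pixels, scale = scale,
                 origin = as.numeric(origin), meta = meta),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image> %d x %d px @ %.4g px/mm (%.4g x %.4g mm)\n",
              nrow(x$pixels), ncol(x$pixels), x$scale,
              ncol(x$pixels) / x$scale, nrow(x$pixels) / x$scale))
  invisible(x)
}

#' @export
dim.raster_image <- function(x) dim(x$pixels)

#' Binary mask container
#'
#' Boolean grid produced by thresholding a [raster_image]. Foreground meaning
#' depends on the analysis mode (pores-bright for grid analysis, ink-dark for
#' filament analysis) and is recorded in `provenance`.
#'
#' @param mask logical matrix.
#' @param scale pixels per millimetre.
#' @param origin world coordinates (mm) of the top-left corner.
#' @param provenance list recording at least the threshold `method`,
#'   threshold `value` and `polarity`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(mask, scale, origin = c(0, 0), provenance = list()) {
  stop_if(!is.matrix(mask) || !is.logical(mask) || any(dim(mask) < 1L),
          "'mask' must be a non-empty logical matrix")
  assert_scalar_pos(scale, "scale")
  structure(list(mask = mask, scale = scale,
                 origin = as.numeric(origin), provenance = provenance),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px @ %.4g px/mm, %.1f%% foreground (%s)\n",
              nrow(x$mask), ncol(x$mask), x$scale, 100 * mean(x$mask),
              x$provenance$method %||% "unknown threshold"))
  invisible(x)
}

#' @export
dim.binary_mask <- function(x) dim(x$mask)

## world mm -> fractional pixel index (column for x, row for y)
world_to_px <- function(v, origin1, scale) (v - origin1) * scale + 0.5

## pixel index -> world mm of the pixel centre
px_to_world <- function(i, origin1, scale) origin1 + (i - 0.5) / scale

#' Write a raster image or mask to disk
#'
#' Writes 8-bit grayscale PNG or TIFF plus (optionally) a JSON sidecar
#' carrying the physical scale, origin and any ground-truth metadata, so that
#' analyses of re-loaded images can recover physical units.
#'
#' @param img a [raster_image] or [binary_mask].
#' @param path output path; format chosen from the extension
#'   (`.png` or `.tif`/`.tiff`).
#' @param sidecar write `<path>.json` with scale/origin/meta? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_raster <- function(img, path, sidecar = TRUE) {
  px <- if (inherits(img, "binary_mask")) img$mask * 1 else img$pixels / 255
  ext <- tolower(tools::file_ext(path))
  ## image files store rows top-to-bottom as-is
  if (ext == "png") {
    png::writePNG(px, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(px, where = path, bits.per.sample = 8L)
  } else stop("unsupported image extension: ", ext, call. = FALSE)
  if (sidecar) {
    meta <- list(scale_px_per_mm = img$scale, origin_mm = img$origin,
                 meta = if (inherits(img, "binary_mask")) img$provenance else img$meta)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a raster image from disk
#'
#' Reads PNG or TIFF (grayscale or RGB; RGB is converted with
#' [to_grayscale()]). The physical scale is taken from the JSON sidecar
#' written by [write_raster()] when present, otherwise it must be supplied --
#' user-supplied photographs always need an explicit px/mm scale.
#'
#' @param path image path.
#' @param scale pixels per mm; overrides any sidecar value when given.
#' @return A [raster_image].
#' @export
read_raster <- function(path, scale = NULL) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext == "png") png::readPNG(path)
         else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else stop("unsupported image extension: ", ext, call. = FALSE)
  origin <- c(0, 0)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    sc <- jsonlite::read_json(side, simplifyVector = TRUE)
    scale <- scale %||% sc$scale_px_per_mm
    if (!is.null(sc$origin_mm)) origin <- as.numeric(sc$origin_mm)
  }
  stop_if(is.null(scale), "no px/mm scale: supply 'scale' or provide a sidecar")
  img <- if (length(dim(arr)) == 3L) {
    to_grayscale(round(arr * 255), scale = scale, origin = origin)
  } else {
    raster_image(round(arr * 255), scale = scale, origin = origin)
  }
  img
}
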
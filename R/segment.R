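#' Convert an image to 8-bit grayscale
#'
#' Luminance-weighted conversion (ITU-R BT.601 weights 0.299/0.587/0.114, the
#' ImageJ default) of an RGB raster to a single 8-bit channel; grayscale
#' input passes through unchanged.
#'
#' @param img a [raster_image], a numeric matrix (grayscale), or a
#'   3-dimensional array with 3 channels in `[0, 255]`.
#' @param scale,origin physical calibration, used when `img` is a bare
#'   matrix/array.
#' @return A [raster_image].
#' @export
to_grayscale <- function(img, scale = NULL, origin = c(0, 0)) {
  if (inherits(img, "raster_image")) return(img)
  if (is.matrix(img)) {
    stop_if(is.null(scale), "'scale' required for bare matrix input")
    return(raster_image(img, scale = scale, origin = origin))
  }
  stop_if(length(dim(img)) != 3L || dim(img)[3] != 3L,
          "unsupported channel count: expected 1 or 3 channels")
  stop_if(is.null(scale), "'scale' required for bare array input")
  g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  raster_image(round(g), scale = scale, origin = origin)
}

#' Threshold an image into a binary mask
#'
#' Global thresholding of an 8-bit grayscale image, either at a fixed value
#' or with Otsu's method computed from the 256-bin histogram. Polarity
#' selects which side of the threshold is foreground: `"bright"` for the
#' grid/porosity analysis (pores appear as bright regions between dark
#' strands) and `"dark"` for filament analysis (the dyed ink itself).
#' The threshold method and value are recorded in the mask's provenance.
#'
#' @param img a [raster_image].
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold threshold value (0-255) when `method = "fixed"`.
#' @param polarity `"bright"`: foreground are pixels `> threshold`;
#'   `"dark"`: foreground are pixels `< threshold`.
#' @return A [binary_mask].
#' @export
binarize <- function(img, method = c("otsu", "fixed"), threshold = NULL,
                     polarity = c("bright", "dark")) {
  stop_if(!inherits(img, "raster_image"), "'img' must be a raster_image")
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  px <- img$pixels
  if (method == "otsu") {
    stop_if(max(px) == min(px), "constant image: Otsu cannot separate classes")
    threshold <- EBImage::otsu(px / 255, range = c(0, 1), levels = 256) * 255
  } else {
    stop_if(is.null(threshold) || !is_scalar_num(threshold),
            "'threshold' required for method = 'fixed'")
  }
  mask <- if (polarity == "bright") px > threshold else px < threshold
  binary_mask(mask, scale = img$scale, origin = img$origin,
              provenance = list(method = method, value = threshold,
                                polarity = polarity))
}

## 4- or 8-connected labelling. EBImage::bwlabel is 4-connected; for
## 8-connectivity, labels touching across a diagonal are merged through a
## components pass on the (small) label adjacency graph.
label_matrix <- function(mask, connectivity = 8L) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (connectivity == 8L && max(lab) > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]     # down-right diagonal
    a2 <- lab[-nr, -1]; b2 <- lab[-1, -nc]     # down-left diagonal
    sel1 <- a1 > 0L & b1 > 0L & a1 != b1
    sel2 <- a2 > 0L & b2 > 0L & a2 != b2
    pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
    if (nrow(pairs) > 0L) {
      g <- igraph::make_empty_graph(n = max(lab), directed = FALSE)
      g <- igraph::add_edges(g, as.vector(t(pairs)))
      memb <- igraph::components(g)$membership
      lab[lab > 0L] <- memb[lab[lab > 0L]]
    }
  }
  ## deterministic sequential labels ordered by first (column-major) pixel
  ids <- lab[lab > 0L]
  if (length(ids) > 0L) {
    first <- tapply(which(lab > 0L), ids, min)
    remap <- integer(max(as.integer(names(first))))
    remap[as.integer(names(first))] <- rank(first, ties.method = "first")
    lab[lab > 0L] <- remap[ids]
  }
  storage.mode(lab) <- "integer"
  lab
}

#' Label and measure particles in a binary mask
#'
#' The analogue of Fiji's "Analyze Particles": labels connected foreground
#' components (8-connected foreground by default, paired with 4-connected
#' background) and measures each one. Area is the pixel count divided by
#' `scale^2`; perimeter is measured on a sub-pixel marching-squares contour
#' of the component (see package vignette for the estimator's bias
#' characteristics); circularity is `4*pi*A/P^2` and the hydraulic radius is
#' `A/P`.
#'
#' @param mask a [binary_mask].
#' @param connectivity 8 (default) or 4.
#' @param smooth_window contour smoothing window (vertices) passed to the
#'   perimeter estimator.
#' @return data.frame of class `particle_records`, one row per particle:
#'   `label`, `area_px`, `area` (mm^2), `perimeter` (mm), `circularity`,
#'   `hydraulic_radius` (mm), `centroid_x`, `centroid_y` (mm),
#'   `touches_border`. The label image is attached as attribute `labels`;
#'   `scale` as attribute `scale`. An empty mask gives zero rows.
#' @export
label_particles <- function(mask, connectivity = 8L, smooth_window = 5L) {
  stop_if(!inherits(mask, "binary_mask"), "'mask' must be a binary_mask")
  stop_if(!connectivity %in% c(4L, 8L), "'connectivity' must be 4 or 8")
  lab <- label_matrix(mask$mask, connectivity)
  n <- max(lab)
  sc <- mask$scale
  rows <- vector("list", n)
  nr <- nrow(lab); nc <- ncol(lab)
  if (n > 0L) {
    idx <- which(lab > 0L)
    ids <- lab[idx]
    rr <- (idx - 1L) %% nr + 1L
    cc <- (idx - 1L) %/% nr + 1L
    for (k in seq_len(n)) {
      sel <- ids == k
      r <- rr[sel]; c <- cc[sel]
      r0 <- min(r); r1 <- max(r); c0 <- min(c); c1 <- max(c)
      sub <- lab[r0:r1, c0:c1, drop = FALSE] == k
      P <- mask_perimeter_px(sub, smooth_window) / sc
      A <- sum(sel) / sc^2
      rows[[k]] <- data.frame(
        label = k, area_px = sum(sel), area = A, perimeter = P,
        ## capped at 1.05, absorbing contour-estimator overshoot on tiny
        ## particles (as ImageJ clamps circularity at 1)
        circularity = min(4 * pi * A / P^2, 1.05), hydraulic_radius = A / P,
        centroid_x = px_to_world(mean(c), mask$origin[1], sc),
        centroid_y = px_to_world(mean(r), mask$origin[2], sc),
        touches_border = r0 == 1L || c0 == 1L || r1 == nr || c1 == nc)
    }
  }
  out <- if (n > 0L) do.call(rbind, rows) else
    data.frame(label = integer(0), area_px = integer(0), area = numeric(0),
               perimeter = numeric(0), circularity = numeric(0),
               hydraulic_radius = numeric(0), centroid_x = numeric(0),
               centroid_y = numeric(0), touches_border = logical(0))
  attr(out, "labels") <- lab
  attr(out, "scale") <- sc
  class(out) <- c("particle_records", class(out))
  out
}

#' Particle filter specification
#'
#' Mirrors the Fiji Analyze Particles filters: minimum size, circularity
#' window and border exclusion. The study's published circularity window of
#' 0.00-0.10 would exclude ideal squares (circularity ~0.785), so the
#' pipeline default keeps the circularity range fully permissive and filters
#' on size plus border exclusion; the published window is available as the
#' `"paper"` preset (see [particle_filter_preset()]).
#'
#' @param min_area minimum area; interpreted in px^2 when `area_unit =
#'   "px"`, in mm^2 when `"mm"`.
#' @param area_unit `"px"` or `"mm"`.
#' @param circularity_range closed interval within `[0, 1.05]` (the upper
#'   cap absorbs contour-estimator overshoot on tiny particles).
#' @param exclude_border drop particles touching the image border?
#' @return An object of class `particle_filter`.
#' @export
particle_filter <- function(min_area = 2.5, area_unit = c("px", "mm"),
                            circularity_range = c(0, 1.05),
                            exclude_border = TRUE) {
  area_unit <- match.arg(area_unit)
  stop_if(!is_scalar_num(min_area) || min_area < 0, "'min_area' must be >= 0")
  stop_if(length(circularity_range) != 2L ||
            circularity_range[1] > circularity_range[2],
          "inverted 'circularity_range' bounds")
  stop_if(any(circularity_range < 0) || any(circularity_range > 1.05),
          "'circularity_range' bounds must lie in [0, 1.05]")
  structure(list(min_area = min_area, area_unit = area_unit,
                 circularity_range = as.numeric(circularity_range),
                 exclude_border = isTRUE(exclude_border)),
            class = "particle_filter")
}

#' Named particle-filter presets
#'
#' `"default"`: min 2.5 px^2, permissive circularity, border exclusion --
#' the pipeline's pore filter. `"paper"`: additionally restricts circularity
#' to 0.00-0.10 as published for the study's ragged real-boundary pores
#' (which excludes ideal rendered squares, so it is not the default).
#'
#' @param name preset name.
#' @return A [particle_filter].
#' @export
particle_filter_preset <- function(name = c("default", "paper")) {
  switch(match.arg(name),
         default = particle_filter(),
         paper = particle_filter(circularity_range = c(0, 0.10)))
}

#' Filter particle records
#'
#' Keeps particles with `area >= min_area`, circularity inside the filter's
#' range and (optionally) not touching the image border; output order is by
#' label, so the result is deterministic.
#'
#' @param records a `particle_records` data.frame from [label_particles()].
#' @param f a [particle_filter].
#' @return The filtered `particle_records`.
#' @export
filter_particles <- function(records, f = particle_filter()) {
  stop_if(!inherits(f, "particle_filter"), "'f' must be a particle_filter")
  area <- if (f$area_unit == "px") records$area_px else records$area
  keep <- area >= f$min_area &
    records$circularity >= f$circularity_range[1] &
    records$circularity <= f$circularity_range[2]
  if (f$exclude_border) keep <- keep & !records$touches_border
  out <- records[keep, , drop = FALSE]
  out <- out[order(out$label), , drop = FALSE]
  for (a in c("labels", "scale")) attr(out, a) <- attr(records, a)
  class(out) <- class(records)
  out
}

#' Porosity of a masked field of view
#'
#' Total pore (foreground) area expressed as a percentage of the analysed
#' field of view, matching the summary porosity of the Fiji workflow.
#'
#' @param mask a [binary_mask] with pores as foreground.
#' @param roi optional rectangle `c(xmin, xmax, ymin, ymax)` in mm (world
#'   coordinates); default is the whole image.
#' @return Porosity in percent.
#' @export
porosity <- function(mask, roi = NULL) {
  stop_if(!inherits(mask, "binary_mask"), "'mask' must be a binary_mask")
  m <- mask$mask
  if (!is.null(roi)) {
    stop_if(length(roi) != 4L || roi[1] >= roi[2] || roi[3] >= roi[4],
            "'roi' must be c(xmin, xmax, ymin, ymax) with positive extent")
    ## pixels whose centres fall inside the roi
    cs <- world_to_px(roi[1:2], mask$origin[1], mask$scale)
    rs <- world_to_px(roi[3:4], mask$origin[2], mask$scale)
    c0 <- max(1L, ceiling(cs[1])); c1 <- min(ncol(m), floor(cs[2]))
    r0 <- max(1L, ceiling(rs[1])); r1 <- min(nrow(m), floor(rs[2]))
    stop_if(c0 > c1 || r0 > r1, "'roi' is empty or outside the image")
    m <- m[r0:r1, c0:c1, drop = FALSE]
  }
  100 * sum(m) / length(m)
}
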
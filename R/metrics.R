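#' Nozzle specification
#' @param gauge label, e.g. `"22G"`.
#' @param inner_diameter inner diameter (mm); the study's 22 G nozzle is
#'   0.41 mm.
#' @return An object of class `nozzle_spec`.
#' @export
nozzle_spec <- function(gauge = "22G", inner_diameter = 0.41) {
  assert_scalar_pos(inner_diameter, "inner_diameter")
  structure(list(gauge = gauge, inner_diameter = inner_diameter),
            class = "nozzle_spec")
}

#' Material constants for the collapse force balance
#'
#' Density and gravity enter the simplified force balance
#' `theta = asin(rho * g * L / sigma0)`; the reference yield stress is the
#' rheometer value the apparent yield stress is compared against. The
#' density default of 1000 kg/m^3 (hydrogels are essentially water-density)
#' reproduces the study's printed apparent yield stresses within rounding.
#'
#' @param density material density (kg/m^3).
#' @param gravity gravitational acceleration (m/s^2).
#' @param reference_yield_stress rheometer yield stress (Pa).
#' @return An object of class `material_params`.
#' @export
material_params <- function(density = 1000, gravity = 9.81,
                            reference_yield_stress = 350) {
  assert_scalar_pos(density, "density")
  assert_scalar_pos(gravity, "gravity")
  assert_scalar_pos(reference_yield_stress, "reference_yield_stress")
  structure(list(density = density, gravity = gravity,
                 reference_yield_stress = reference_yield_stress),
            class = "material_params")
}

#' Measure filament width from a binary mask
#'
#' Samples the strand width as foreground extent on cross-sections taken
#' every pixel along the filament axis, excluding a fractional margin at both
#' ends. The axis is either a coordinate axis or (default) the principal
#' axis of the foreground pixels, which makes the measurement insensitive to
#' small print/camera misalignment: pixel centres are projected onto the
#' axis, binned at one-pixel pitch, and each bin's width is its pixel count
#' times the pixel pitch. Cross-sections with no foreground (a broken
#' filament) are flagged, excluded from the mean and reported.
#'
#' @param mask a [binary_mask] with the filament as foreground.
#' @param axis `"auto"` (principal axis), `"x"` or `"y"`.
#' @param end_margin fraction of the along-axis extent excluded at each end
#'   (default 0.05).
#' @return list with `mean_width`, `width_sd` (mm), `n_sections`,
#'   `n_broken`, and the per-section `widths`.
#' @export
measure_line_width <- function(mask, axis = c("auto", "x", "y"),
                               end_margin = 0.05) {
  stop_if(!inherits(mask, "binary_mask"), "'mask' must be a binary_mask")
  axis <- match.arg(axis)
  sc <- mask$scale
  idx <- which(mask$mask)
  stop_if(length(idx) == 0L, "empty mask: no filament to measure")
  nr <- nrow(mask$mask)
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  u <- switch(axis,
              x = c(1, 0), y = c(0, 1),
              auto = {
                xy <- cbind(c - mean(c), r - mean(r))
                ev <- eigen(crossprod(xy) / nrow(xy), symmetric = TRUE)
                ev$vectors[, 1]
              })
  proj <- c * u[1] + r * u[2]
  lo <- min(proj); hi <- max(proj)
  span <- hi - lo
  lo2 <- lo + end_margin * span; hi2 <- hi - end_margin * span
  keep <- proj >= lo2 & proj <= hi2
  stop_if(!any(keep), "measurement window is empty")
  bins <- floor((proj[keep] - lo2))          # 1 px pitch along the axis
  counts <- tabulate(bins + 1L, nbins = max(bins) + 1L)
  broken <- counts == 0L
  widths <- counts[!broken] / sc
  list(mean_width = mean(widths), width_sd = stats::sd(widths),
       n_sections = length(widths), n_broken = sum(broken),
       widths = widths)
}

#' Spreading ratio
#'
#' Printed filament width divided by the nozzle inner diameter
#' (`SR = w_ext / d_nozzle`); 1.0 is ideal fidelity, hydrogels under
#' pneumatic extrusion typically reach 1.8 or more from die swell.
#'
#' @param w_ext measured filament width (mm).
#' @param nozzle a [nozzle_spec] (or a bare inner diameter in mm).
#' @return The dimensionless spreading ratio.
#' @export
spreading_ratio <- function(w_ext, nozzle = nozzle_spec()) {
  assert_scalar_pos(w_ext, "w_ext")
  d <- if (inherits(nozzle, "nozzle_spec")) nozzle$inner_diameter else nozzle
  assert_scalar_pos(d, "nozzle inner diameter")
  w_ext / d
}

#' Uniformity ratio of a filament
#'
#' Compares the actual boundary perimeter of the extruded line (`p_ext`,
#' measured on the sub-pixel contour of the region clipped to the
#' measurement window) to its theoretical smooth perimeter. The theoretical
#' perimeter uses the mean *measured* width,
#' `p_th = 2 * segment_length + 2 * mean_width`, which isolates boundary
#' roughness from spreading -- consistent with uniformity staying near 1
#' while the spreading ratio reaches 1.8.
#'
#' @param mask a [binary_mask] with the filament as foreground (one region).
#' @param axis measurement axis, as in [measure_line_width()].
#' @param end_margin fraction of the along-axis extent clipped at each end
#'   before measuring (default 0.05).
#' @param smooth_window contour smoothing window (vertices).
#' @return list with `p_ext`, `p_th`, `segment_length`, `mean_width` (mm)
#'   and `UF = p_ext / p_th`.
#' @export
uniformity_ratio <- function(mask, axis = c("x", "y"), end_margin = 0.05,
                             smooth_window = 5L) {
  stop_if(!inherits(mask, "binary_mask"), "'mask' must be a binary_mask")
  axis <- match.arg(axis)
  m <- mask$mask
  if (axis == "y") m <- t(m)
  cols <- which(colSums(m) > 0L)
  stop_if(length(cols) == 0L, "empty mask")
  span <- max(cols) - min(cols) + 1L
  c0 <- min(cols) + floor(end_margin * span)
  c1 <- max(cols) - floor(end_margin * span)
  sub <- m[, c0:c1, drop = FALSE]
  rows <- which(rowSums(sub) > 0L)
  sub <- sub[min(rows):max(rows), , drop = FALSE]
  ## a single filament region must remain after clipping
  ncomp <- max(label_matrix(sub, 8L))
  stop_if(ncomp != 1L, sprintf("expected one filament region in window, found %d", ncomp))
  sc <- mask$scale
  p_ext <- mask_perimeter_px(sub, smooth_window) / sc
  sub_mask <- binary_mask(sub, scale = sc)
  wm <- measure_line_width(sub_mask, axis = "x", end_margin = 0)
  seg_len <- ncol(sub) / sc
  p_th <- 2 * seg_len + 2 * wm$mean_width
  list(p_ext = p_ext, p_th = p_th, segment_length = seg_len,
       mean_width = wm$mean_width, UF = p_ext / p_th)
}

#' Full line-test metrics
#'
#' Convenience wrapper for the straight-line print test: measures width
#' (mean and SD), spreading ratio against the nozzle and uniformity ratio on
#' one mask.
#'
#' @param mask a [binary_mask] with the filament as foreground.
#' @param nozzle a [nozzle_spec].
#' @param axis measurement axis for the uniformity clip window.
#' @return list with `mean_width`, `width_sd`, `SR`, `p_ext`, `p_th`, `UF`.
#' @export
line_metrics <- function(mask, nozzle = nozzle_spec(), axis = "x") {
  wm <- measure_line_width(mask, axis = "auto")
  uf <- uniformity_ratio(mask, axis = axis)
  list(mean_width = wm$mean_width, width_sd = wm$width_sd,
       SR = spreading_ratio(wm$mean_width, nozzle),
       p_ext = uf$p_ext, p_th = uf$p_th, UF = uf$UF)
}

#' Printability index of a pore
#'
#' `Pr = L^2 / (16 A)` for pore perimeter `L` and area `A`: exactly 1 for a
#' perfect square, `pi/4` for a disk (rounded pores, under-gelled inks),
#' above 1 for ragged or elongated pores (over-gelled inks or irregular
#' extrusion).
#'
#' @param p a `particle_records` row (or data.frame; vectorised), or a bare
#'   perimeter in mm if `area` is given.
#' @param area pore area (mm^2) when `p` is a bare perimeter.
#' @return The printability index (vector if `p` has several rows).
#' @export
printability_index <- function(p, area = NULL) {
  if (is.data.frame(p)) {
    stop_if(any(p$area <= 0) || any(p$perimeter <= 0),
            "particles must have positive area and perimeter")
    return(p$perimeter^2 / (16 * p$area))
  }
  stop_if(is.null(area), "'area' required when 'p' is a bare perimeter")
  stop_if(any(p <= 0) || any(area <= 0), "perimeter and area must be positive")
  p^2 / (16 * area)
}
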
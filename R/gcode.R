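#' Unit-area filament diameter
#'
#' The "diameter trick" of volumetric extrusion calibration: declaring a
#' theoretical filament diameter of `2/sqrt(pi) = 1.12838 mm` makes the
#' implied cross-sectional area exactly 1 mm^2, so every 1 mm of commanded E
#' corresponds to exactly 1 mm^3 of ink.
#'
#' @return `2 / sqrt(pi)` (mm).
#' @export
effective_unit_diameter <- function() 2 / sqrt(pi)

#' Volumetric extrusion calibration
#'
#' Captures the calibration that locks G-code E values to physical volume on
#' a positive-displacement (screw) extruder: with the unit-area filament
#' diameter, 1 E-unit = 1 mm^3, and a `rotation_distance` of 10 mm^3/rev
#' aligns a 10 mm E command with exactly one pump revolution. The
#' `extrusion_factor` scales the commanded volume (deliberate under-extrusion
#' at < 1).
#'
#' @param filament_diameter theoretical filament diameter (mm); must imply a
#'   1 mm^2 cross-section within 1e-4 when equal to
#'   [effective_unit_diameter()].
#' @param rotation_distance extruded volume per motor revolution (mm^3/rev).
#' @param extrusion_factor commanded fraction of the theoretical volume,
#'   in (0, 1].
#' @return An object of class `volumetric_calibration`.
#' @export
volumetric_calibration <- function(filament_diameter = effective_unit_diameter(),
                                   rotation_distance = 10,
                                   extrusion_factor = 1) {
  assert_scalar_pos(filament_diameter, "filament_diameter")
  assert_scalar_pos(rotation_distance, "rotation_distance")
  stop_if(!is_scalar_num(extrusion_factor) || extrusion_factor <= 0 ||
            extrusion_factor > 1, "'extrusion_factor' must be in (0, 1]")
  area <- pi * (filament_diameter / 2)^2
  stop_if(abs(filament_diameter - effective_unit_diameter()) < 1e-9 &&
            abs(area - 1) > 1e-4,
          "unit-diameter calibration must imply a 1 mm^2 cross-section")
  structure(list(filament_diameter = filament_diameter,
                 cross_section_area = area,
                 rotation_distance = rotation_distance,
                 extrusion_factor = extrusion_factor),
            class = "volumetric_calibration")
}

fmt4 <- function(x) formatC(x, format = "f", digits = 4)

#' Serialize a toolpath as volumetrically calibrated G-code
#'
#' Emits absolute-XY (G90), absolute-E (M82), millimetre (G21) G-code.
#' For each extrude segment the E increment is
#' `length x width x layer_height x extrusion_factor` in mm^3 -- with the
#' unit-area calibration, 1 E-unit = 1 mm^3. Travel moves emit no E.
#' Coordinates and E are formatted to 4 decimals; feedrate is `speed` in
#' mm/min units.
#'
#' @param t a [toolpath]; extrude segments must carry commanded widths.
#' @param cal a [volumetric_calibration].
#' @param speed print speed (mm/s).
#' @param layer_height layer height (mm); defaults to the toolpath's
#'   `meta$layer_height`.
#' @return Character vector of G-code lines.
#' @export
to_gcode <- function(t, cal = volumetric_calibration(), speed = 20,
                     layer_height = NULL) {
  stop_if(!inherits(t, "toolpath"), "'t' must be a toolpath")
  stop_if(!inherits(cal, "volumetric_calibration"), "'cal' must be a volumetric_calibration")
  assert_scalar_pos(speed, "speed")
  layer_height <- layer_height %||% t$meta$layer_height
  stop_if(is.null(layer_height) || !is_scalar_num(layer_height) || layer_height <= 0,
          "'layer_height' must be a positive number on extruding toolpaths")
  v <- t$vertices
  stop_if(any(v$extrude %in% TRUE & (is.na(v$width) | v$width <= 0)),
          "extrude segments must carry width > 0")
  f_mm_min <- fmt4(speed * 60)
  lines <- c(
    sprintf("; bioprintqc pattern=%s", t$pattern),
    sprintf("; calibration: filament_diameter=%.5f mm (area=%.6f mm^2)",
            cal$filament_diameter, cal$cross_section_area),
    sprintf("; calibration: rotation_distance=%.4f mm^3/rev extrusion_factor=%.4f",
            cal$rotation_distance, cal$extrusion_factor),
    sprintf("; layer_height=%.4f mm speed=%.2f mm/s", layer_height, speed),
    "G21", "G90", "M82", "G92 E0")
  e <- 0
  cur_layer <- NA_integer_
  for (i in seq_len(nrow(v))) {
    if (!identical(cur_layer, v$layer[i])) {
      cur_layer <- v$layer[i]
      lines <- c(lines, sprintf("; layer %d", cur_layer),
                 sprintf("G0 Z%s", fmt4(cur_layer * layer_height)))
    }
    if (i == 1L || is.na(v$extrude[i])) {
      lines <- c(lines, sprintf("G0 X%s Y%s", fmt4(v$x[i]), fmt4(v$y[i])))
    } else if (v$extrude[i]) {
      len <- sqrt((v$x[i] - v$x[i - 1])^2 + (v$y[i] - v$y[i - 1])^2)
      e <- e + len * v$width[i] * layer_height * cal$extrusion_factor
      lines <- c(lines, sprintf("G1 X%s Y%s E%s F%s",
                                fmt4(v$x[i]), fmt4(v$y[i]), fmt4(e), f_mm_min))
    } else {
      lines <- c(lines, sprintf("G0 X%s Y%s", fmt4(v$x[i]), fmt4(v$y[i])))
    }
  }
  lines <- c(lines, sprintf("; total E = %s mm^3 (%.4f pump revolutions)",
                            fmt4(e), e / cal$rotation_distance))
  lines
}

#' Write G-code to file
#' @param gcode character vector from [to_gcode()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gcode <- function(gcode, path) {
  writeLines(gcode, path)
  invisible(path)
}

#' Minimal G-code parser
#'
#' Recovers vertex coordinates, per-move absolute E and Z from G-code in the
#' dialect written by [to_gcode()] (absolute XY/E, mm). Intended for
#' round-trip verification of generated programs, not as a general slicer
#' parser.
#'
#' @param gcode character vector of G-code lines (or a file path).
#' @return data.frame with columns `x`, `y`, `z`, `e`, `extrude` (logical:
#'   did this move increment E).
#' @export
parse_gcode <- function(gcode) {
  if (length(gcode) == 1L && file.exists(gcode)) gcode <- readLines(gcode)
  gcode <- sub(";.*$", "", gcode)
  gcode <- trimws(gcode)
  gcode <- gcode[grepl("^G[01]\\b", gcode)]
  num <- function(line, key) {
    m <- regmatches(line, regexpr(paste0(key, "-?[0-9.]+"), line))
    if (length(m) == 0L) NA_real_ else as.numeric(sub(key, "", m))
  }
  x <- y <- z <- NA_real_; e <- 0
  out <- vector("list", length(gcode))
  for (i in seq_along(gcode)) {
    l <- gcode[i]
    has_xy <- grepl("[XY]-?[0-9]", l)
    x <- if (!is.na(v <- num(l, "X"))) v else x
    y <- if (!is.na(v <- num(l, "Y"))) v else y
    z <- if (!is.na(v <- num(l, "Z"))) v else z
    enew <- num(l, "E")
    ext <- !is.na(enew) && enew > e
    if (!is.na(enew)) e <- enew
    ## Z-only moves update state but are not vertices
    if (has_xy) out[[i]] <- data.frame(x = x, y = y, z = z, e = e, extrude = ext)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  res[!is.na(res$x), , drop = FALSE]
}
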
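#' Deposition model for synthetic top-view rendering
#'
#' Statistical model of how a commanded toolpath turns into deposited ink in
#' a top-view photograph: multiplicative spreading of the strand width (die
#' swell), band-limited boundary roughness, corner rounding / gel
#' accumulation at junctions and crossings, and geometric fusion of strands
#' whose edge-to-edge gap falls at or below `fusion_gap`. All randomness is
#' driven by `seed`, so renders are deterministic.
#'
#' @param spread_ratio multiplier on the commanded width (> 0); 1 is ideal
#'   fidelity, hydrogels typically spread to 1.0-1.9.
#' @param roughness_amplitude boundary-normal perturbation amplitude (mm,
#'   >= 0); must stay below the strand half-width.
#' @param roughness_wavelength characteristic wavelength of the boundary
#'   perturbation (mm).
#' @param corner_round_radius extra radius (mm) of the gel blob stamped at
#'   path junctions and strand crossings; 0 disables corner rounding.
#' @param fusion_gap edge-to-edge distance (mm) at or below which adjacent
#'   strands merge into one region.
#' @param seed integer RNG seed for the roughness profile.
#' @return An object of class `deposition_model`.
#' @export
deposition_model <- function(spread_ratio = 1, roughness_amplitude = 0,
                             roughness_wavelength = 1.5,
                             corner_round_radius = 0, fusion_gap = 0,
                             seed = 1L) {
  assert_scalar_pos(spread_ratio, "spread_ratio")
  stop_if(!is_scalar_num(roughness_amplitude) || roughness_amplitude < 0,
          "'roughness_amplitude' must be >= 0")
  assert_scalar_pos(roughness_wavelength, "roughness_wavelength")
  stop_if(!is_scalar_num(corner_round_radius) || corner_round_radius < 0,
          "'corner_round_radius' must be >= 0")
  stop_if(!is_scalar_num(fusion_gap) || fusion_gap < 0,
          "'fusion_gap' must be >= 0")
  structure(list(spread_ratio = spread_ratio,
                 roughness_amplitude = roughness_amplitude,
                 roughness_wavelength = roughness_wavelength,
                 corner_round_radius = corner_round_radius,
                 fusion_gap = fusion_gap, seed = as.integer(seed)),
            class = "deposition_model")
}

## Band-limited boundary roughness: one smooth function of path arclength per
## strand side, built from 8 cosines with wavelengths scattered around the
## nominal wavelength and amplitudes normalised so the RMS equals that of a
## single sinusoid of amplitude `roughness_amplitude`. Zero-mean, so the mean
## strand width is unchanged.
roughness_profiles <- function(m) {
  if (m$roughness_amplitude == 0) {
    f0 <- function(s) rep(0, length(s))
    return(list(left = f0, right = f0))
  }
  with_seed(m$seed, {
    mk <- function() {
      k <- 8L
      lam <- m$roughness_wavelength * stats::runif(k, 0.7, 1.4)
      phi <- stats::runif(k, 0, 2 * pi)
      a <- stats::runif(k, 0.5, 1)
      a <- a * m$roughness_amplitude / sqrt(sum(a^2))
      function(s) {
        out <- 0
        for (j in seq_len(k)) out <- out + a[j] * cos(2 * pi * s / lam[j] + phi[j])
        out
      }
    }
    list(left = mk(), right = mk())
  })
}

## Intersection points of two segments (interior crossings only).
seg_crossing <- function(a, b) {
  d1 <- c(a$x1 - a$x0, a$y1 - a$y0)
  d2 <- c(b$x1 - b$x0, b$y1 - b$y0)
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-12) return(NULL)
  dx <- b$x0 - a$x0; dy <- b$y0 - a$y0
  t1 <- (dx * d2[2] - dy * d2[1]) / den
  t2 <- (dx * d1[2] - dy * d1[1]) / den
  eps <- 1e-9
  if (t1 < eps || t1 > 1 - eps || t2 < eps || t2 > 1 - eps) return(NULL)
  c(a$x0 + t1 * d1[1], a$y0 + t1 * d1[2])
}

## Fill a disc of radius r (mm) centred at (cx, cy) into logical matrix ink.
stamp_disc <- function(ink, cx, cy, r, origin, scale) {
  nr <- nrow(ink); nc <- ncol(ink)
  c0 <- max(1L, floor(world_to_px(cx - r, origin[1], scale)))
  c1 <- min(nc, ceiling(world_to_px(cx + r, origin[1], scale)))
  r0 <- max(1L, floor(world_to_px(cy - r, origin[2], scale)))
  r1 <- min(nr, ceiling(world_to_px(cy + r, origin[2], scale)))
  if (c0 > c1 || r0 > r1) return(ink)
  xs <- px_to_world(c0:c1, origin[1], scale) - cx
  ys <- px_to_world(r0:r1, origin[2], scale) - cy
  d2 <- outer(ys^2, xs^2, "+")
  ink[r0:r1, c0:c1] <- ink[r0:r1, c0:c1] | (d2 <= r^2)
  ink
}

#' Render a top-view image of a deposited toolpath
#'
#' Draws the extruded strands dark on a light background (the study's ink is
#' dyed for contrast) at width `commanded_width x spread_ratio`, perturbs the
#' strand boundary with the model's seeded roughness, stamps rounded gel
#' blobs at junctions/crossings when `corner_round_radius > 0`, and merges
#' strands whose edge gap is at or below `fusion_gap` (morphological closing
#' with a disc of that diameter). Deterministic for a fixed model seed.
#'
#' @param t a [toolpath] (planar; layers are unioned in top view).
#' @param m a [deposition_model].
#' @param scale pixels per mm (>= 10).
#' @param margin background margin around the toolpath bounding box (mm).
#' @param ink_value,background_value 8-bit intensities of strand and
#'   background pixels.
#' @return A [raster_image] whose `meta` records the model, scale and
#'   ground-truth rendered widths.
#' @export
render_topview <- function(t, m, scale = 20, margin = 2,
                           ink_value = 40, background_value = 220) {
  stop_if(!inherits(t, "toolpath"), "'t' must be a toolpath")
  stop_if(!inherits(m, "deposition_model"), "'m' must be a deposition_model")
  stop_if(!is_scalar_num(scale) || scale < 10, "'scale' must be >= 10 px/mm")
  seg <- toolpath_segments(t)
  seg <- seg[seg$extrude, , drop = FALSE]
  stop_if(nrow(seg) == 0L, "toolpath has no extrude segments")
  rw <- seg$width * m$spread_ratio
  stop_if(any(rw * scale < 2),
          "under-resolved: rendered strand width < 2 px at this scale")
  stop_if(m$roughness_amplitude >= min(rw) / 2,
          "'roughness_amplitude' must be below the strand half-width")
  xmin <- min(seg$x0, seg$x1) - margin; xmax <- max(seg$x0, seg$x1) + margin
  ymin <- min(seg$y0, seg$y1) - margin; ymax <- max(seg$y0, seg$y1) + margin
  nc <- ceiling((xmax - xmin) * scale); nr <- ceiling((ymax - ymin) * scale)
  origin <- c(xmin, ymin)
  ink <- matrix(FALSE, nr, nc)
  rough <- roughness_profiles(m)
  pad <- m$roughness_amplitude * 2.5 + 2 / scale

  ## cumulative extruded arclength at segment start keeps roughness
  ## continuous along the path
  s0 <- cumsum(c(0, seg$length))[seq_len(nrow(seg))]
  for (i in seq_len(nrow(seg))) {
    h <- rw[i] / 2
    c0 <- max(1L, floor(world_to_px(min(seg$x0[i], seg$x1[i]) - h - pad, origin[1], scale)))
    c1 <- min(nc, ceiling(world_to_px(max(seg$x0[i], seg$x1[i]) + h + pad, origin[1], scale)))
    r0 <- max(1L, floor(world_to_px(min(seg$y0[i], seg$y1[i]) - h - pad, origin[2], scale)))
    r1 <- min(nr, ceiling(world_to_px(max(seg$y0[i], seg$y1[i]) + h + pad, origin[2], scale)))
    if (c0 > c1 || r0 > r1) next
    xs <- px_to_world(c0:c1, origin[1], scale)
    ys <- px_to_world(r0:r1, origin[2], scale)
    L <- seg$length[i]
    ux <- (seg$x1[i] - seg$x0[i]) / L; uy <- (seg$y1[i] - seg$y0[i]) / L
    ## along-path (s) and boundary-normal (d) coordinates of pixel centres
    s <- outer(uy * (ys - seg$y0[i]), ux * (xs - seg$x0[i]), "+")
    d <- outer(ux * (ys - seg$y0[i]), -uy * (xs - seg$x0[i]), "+")
    if (m$roughness_amplitude > 0) {
      sa <- s0[i] + pmin(pmax(s, 0), L)
      hL <- h + pmin(rough$left(sa), 0.45 * rw[i])
      hR <- h + pmin(rough$right(sa), 0.45 * rw[i])
      inside <- s >= 0 & s <= L & ifelse(d >= 0, d <= hL, -d <= hR)
    } else {
      inside <- s >= 0 & s <= L & abs(d) <= h
    }
    blk <- ink[r0:r1, c0:c1]
    ink[r0:r1, c0:c1] <- blk | inside
  }

  ## round joins where consecutive extrude segments share a vertex, and gel
  ## blobs at junctions/crossings when corner rounding is on
  v <- t$vertices
  for (i in 2:(nrow(v) - 1L)) {
    if (isTRUE(v$extrude[i]) && isTRUE(v$extrude[i + 1L])) {
      h <- max(v$width[i], v$width[i + 1L]) * m$spread_ratio / 2
      ink <- stamp_disc(ink, v$x[i], v$y[i], h + m$corner_round_radius,
                        origin, scale)
    }
  }
  if (m$corner_round_radius > 0 && nrow(seg) > 1L) {
    for (i in seq_len(nrow(seg) - 1L)) for (j in (i + 1L):nrow(seg)) {
      p <- seg_crossing(seg[i, ], seg[j, ])
      if (!is.null(p)) {
        h <- max(rw[i], rw[j]) / 2
        ink <- stamp_disc(ink, p[1], p[2], h + m$corner_round_radius,
                          origin, scale)
      }
    }
  }

  if (m$fusion_gap > 0) {
    sz <- 2L * floor(m$fusion_gap * scale / 2) + 1L
    if (sz >= 3L) {
      ink <- EBImage::closing(ink * 1, EBImage::makeBrush(sz, "disc")) > 0.5
    }
  }

  px <- matrix(background_value, nr, nc)
  px[ink] <- ink_value
  raster_image(px, scale = scale, origin = origin,
               meta = list(model = unclass(m), pattern = t$pattern,
                           rendered_widths = rw,
                           toolpath_meta = t$meta))
}

#' Parabolic sag model for side-view rendering
#'
#' Geometry of a filament suspended between two pillars: a parabolic
#' centerline (the uniform-load, small-deflection limit) with midspan sag
#' `max_sag` over `span`. The slope at the supports is the parabolic identity
#' `4 * max_sag / span`, which parameterises the collapse angle cleanly.
#'
#' @param span clear gap between the pillars (mm).
#' @param max_sag midspan deflection (mm, >= 0).
#' @param filament_thickness rendered filament thickness (mm).
#' @param pillar_width,pillar_height fixture pillar geometry (mm).
#' @return An object of class `sag_model` with a precomputed
#'   `support_slope`.
#' @export
sag_model <- function(span, max_sag, filament_thickness = 0.8,
                      pillar_width = 2, pillar_height = 10) {
  assert_scalar_pos(span, "span")
  stop_if(!is_scalar_num(max_sag) || max_sag < 0, "'max_sag' must be >= 0")
  assert_scalar_pos(filament_thickness, "filament_thickness")
  assert_scalar_pos(pillar_width, "pillar_width")
  assert_scalar_pos(pillar_height, "pillar_height")
  stop_if(max_sag > pillar_height, "'max_sag' cannot exceed the pillar height")
  structure(list(span = span, max_sag = max_sag,
                 filament_thickness = filament_thickness,
                 pillar_width = pillar_width, pillar_height = pillar_height,
                 support_slope = 4 * max_sag / span),
            class = "sag_model")
}

#' Render a side-view image of a sagging suspended filament
#'
#' Draws the filament as a dark band of constant vertical thickness along the
#' parabolic centerline between two pillar tops, plus the supporting pillars.
#' Support x positions and the pillar-top line are annotated in metadata for
#' the collapse-angle and collapse-rate measurements.
#'
#' @param s a [sag_model].
#' @param scale pixels per mm; must resolve the filament thickness by at
#'   least 3 px.
#' @param margin background margin (mm).
#' @param floor_depth rendered depth below the pillar top (mm); sets the
#'   image height.
#' @param ink_value,background_value 8-bit intensities.
#' @return A [raster_image] with `meta$support_x` (world mm of the two
#'   supports), `meta$pillar_top_y` and the ground-truth sag parameters.
#' @export
render_sideview <- function(s, scale = 20, margin = 2, floor_depth = NULL,
                            ink_value = 40, background_value = 220) {
  stop_if(!inherits(s, "sag_model"), "'s' must be a sag_model")
  stop_if(s$filament_thickness * scale < 3,
          "'scale' must resolve the filament thickness by >= 3 px")
  L <- s$span; tft <- s$filament_thickness
  floor_depth <- floor_depth %||% min(s$pillar_height, s$max_sag + tft + 2)
  xmin <- -s$pillar_width - margin; xmax <- L + s$pillar_width + margin
  y_center <- margin + tft / 2            # centerline height at the supports
  pillar_top <- y_center + tft / 2
  ymax <- pillar_top + floor_depth
  nc <- ceiling((xmax - xmin) * scale); nr <- ceiling(ymax * scale)
  origin <- c(xmin, 0)
  xs <- px_to_world(seq_len(nc), origin[1], scale)
  ys <- px_to_world(seq_len(nr), origin[2], scale)
  ink <- matrix(FALSE, nr, nc)
  ## filament: parabolic centerline between the supports (y grows downward)
  inspan <- xs >= 0 & xs <= L
  yc <- y_center + 4 * s$max_sag * xs * (L - xs) / L^2
  for (j in which(inspan)) ink[abs(ys - yc[j]) <= tft / 2, j] <- TRUE
  ## pillars outside the span, from the pillar top downward
  pil <- (xs >= -s$pillar_width & xs < 0) | (xs > L & xs <= L + s$pillar_width)
  ink[ys >= pillar_top, pil] <- TRUE
  px <- matrix(background_value, nr, nc)
  px[ink] <- ink_value
  raster_image(px, scale = scale, origin = origin,
               meta = list(support_x = c(0, L), pillar_top_y = pillar_top,
                           floor_depth = floor_depth, sag = unclass(s)))
}

#' Apply camera imperfections to a rendered image
#'
#' Multiplies the image by a linear illumination ramp (brightest at the left
#' edge, `1 + illum_gradient` relative to the right edge) and adds seeded
#' Gaussian intensity noise, clipping to 0-255. Emulates the residual
#' non-uniformity of overhead illumination and sensor noise in the
#' photographs the segmentation workflow has to cope with. Deterministic per
#' seed.
#'
#' @param img a [raster_image].
#' @param illum_gradient fractional left/right illumination ratio minus one,
#'   in `[0, 1)`.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param seed integer RNG seed.
#' @return A [raster_image].
#' @export
apply_camera_noise <- function(img, illum_gradient = 0, noise_sd = 0, seed = 1L) {
  stop_if(!inherits(img, "raster_image"), "'img' must be a raster_image")
  stop_if(!is_scalar_num(illum_gradient) || illum_gradient < 0 || illum_gradient >= 1,
          "'illum_gradient' must be in [0, 1)")
  stop_if(!is_scalar_num(noise_sd) || noise_sd < 0, "'noise_sd' must be >= 0")
  px <- img$pixels
  nc <- ncol(px)
  if (illum_gradient > 0 && nc > 1L) {
    ramp <- 1 + illum_gradient * (nc - seq_len(nc)) / (nc - 1)
    px <- sweep(px, 2L, ramp, "*")
  }
  if (noise_sd > 0) {
    px <- px + with_seed(seed, matrix(stats::rnorm(length(px), 0, noise_sd),
                                      nrow(px), ncol(px)))
  }
  px <- round(pmin(pmax(px, 0), 255))
  raster_image(px, scale = img$scale, origin = img$origin,
               meta = c(img$meta, list(illum_gradient = illum_gradient,
                                       noise_sd = noise_sd, noise_seed = seed)))
}
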
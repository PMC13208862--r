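#' Deflection angle of a suspended filament
#'
#' Measures the collapse angle theta -- the angle between the pillar-top
#' horizontal and the suspended filament at the supports -- from a side-view
#' binary mask. The filament centerline is extracted per image column as the
#' mean row of foreground pixels; a local polynomial is fitted to the
#' centerline over a window extending `fit_window` mm inward from each
#' support and theta is the mean of the two absolute support-tangent angles.
#'
#' The default fit is quadratic with the tangent evaluated at the support:
#' on a curved (sagging) centerline a straight-line fit returns the tangent
#' at the window midpoint and systematically underestimates the support
#' angle (about 0.5 degrees for a 1.3 mm sag over 32 mm with a 2 mm window),
#' while the quadratic tangent is exact for a parabolic profile. `fit =
#' "linear"` is retained for comparison.
#'
#' @param mask a [binary_mask] of the side view with the filament (and
#'   possibly pillars) as foreground.
#' @param support_x numeric length-2: world x (mm) of the two supports
#'   (inner pillar edges); must lie inside the image.
#' @param fit_window window length (mm) inward from each support.
#' @param fit `"quadratic"` (default) or `"linear"`.
#' @return list with `theta_deg` (mean of the two sides), `theta_left`,
#'   `theta_right`, `n_broken` (columns without foreground between the
#'   supports) and `ruptured` (no foreground at all between supports).
#' @export
collapse_angle <- function(mask, support_x, fit_window = 2,
                           fit = c("quadratic", "linear")) {
  stop_if(!inherits(mask, "binary_mask"), "'mask' must be a binary_mask")
  fit <- match.arg(fit)
  stop_if(length(support_x) != 2L, "'support_x' must have two elements")
  support_x <- sort(as.numeric(support_x))
  assert_scalar_pos(fit_window, "fit_window")
  sc <- mask$scale
  m <- mask$mask
  xs <- px_to_world(seq_len(ncol(m)), mask$origin[1], sc)
  stop_if(min(support_x) < min(xs) || max(support_x) > max(xs),
          "supports must lie inside the image")
  centerline <- function(cols) {
    y <- vapply(cols, function(j) {
      r <- which(m[, j])
      if (length(r) == 0L) NA_real_ else mean(r)
    }, numeric(1))
    px_to_world(y, mask$origin[2], sc)
  }
  span_cols <- which(xs > support_x[1] & xs < support_x[2])
  ycl <- centerline(span_cols)
  if (all(is.na(ycl)))
    return(list(theta_deg = NA_real_, theta_left = NA_real_,
                theta_right = NA_real_, n_broken = length(span_cols),
                ruptured = TRUE))
  side_angle <- function(x0, dir) {
    cols <- span_cols[xs[span_cols] >= min(x0, x0 + dir * fit_window) &
                      xs[span_cols] <= max(x0, x0 + dir * fit_window)]
    x <- xs[cols]; y <- centerline(cols)
    ok <- !is.na(y)
    stop_if(sum(ok) < 4L, "too few centerline columns in the fit window")
    x <- x[ok] - x0; y <- y[ok]
    slope <- if (fit == "quadratic") {
      co <- stats::lm(y ~ x + I(x^2))$coefficients
      co[[2]]                        # tangent at the support (x = 0)
    } else {
      stats::lm(y ~ x)$coefficients[[2]]
    }
    atan(abs(slope)) * 180 / pi
  }
  th_l <- side_angle(support_x[1], +1)
  th_r <- side_angle(support_x[2], -1)
  list(theta_deg = mean(c(th_l, th_r)), theta_left = th_l, theta_right = th_r,
       n_broken = sum(is.na(ycl)), ruptured = FALSE)
}

#' Collapse rate of a suspended filament
#'
#' Area-based collapse metric `Cf = 100 * (Act - Aca) / Act`, where `Act =
#' span x reference_depth` is the theoretical rectangular area under a
#' straight filament and `Aca` is the actual area under the sagging one.
#' The sagged area is integrated per column as the depth of the filament's
#' lower boundary below the straight pillar-top chord (the declared
#' convention; whether the filament's own cross-section belongs to `Aca` is
#' not observable from the metric's definition).
#'
#' @param mask a [binary_mask] of the side view.
#' @param support_x world x (mm) of the two supports.
#' @param pillar_top_y world y (mm) of the pillar-top line (the chord).
#' @param reference_depth depth (mm) of the reference floor below the
#'   pillar top.
#' @return list with `Cf` (percent), `Act`, `Aca`, `sag_area` (mm^2),
#'   `span` (mm).
#' @export
collapse_rate <- function(mask, support_x, pillar_top_y, reference_depth) {
  stop_if(!inherits(mask, "binary_mask"), "'mask' must be a binary_mask")
  stop_if(length(support_x) != 2L, "'support_x' must have two elements")
  assert_scalar_pos(reference_depth, "reference_depth")
  support_x <- sort(as.numeric(support_x))
  sc <- mask$scale
  m <- mask$mask
  xs <- px_to_world(seq_len(ncol(m)), mask$origin[1], sc)
  cols <- which(xs > support_x[1] & xs < support_x[2])
  stop_if(length(cols) == 0L, "no columns between the supports")
  depth <- vapply(cols, function(j) {
    r <- which(m[, j])
    if (length(r) == 0L) return(NA_real_)
    ## the 0.5-iso lower boundary sits half a pixel below the last
    ## foreground pixel centre
    y_bot <- px_to_world(max(r) + 0.5, mask$origin[2], sc)
    max(0, y_bot - pillar_top_y)
  }, numeric(1))
  stop_if(any(depth > reference_depth + 1e-9, na.rm = TRUE),
          "filament lies below the reference floor")
  sag_area <- sum(depth, na.rm = TRUE) / sc
  span <- diff(support_x)
  act <- span * reference_depth
  list(Cf = 100 * sag_area / act, Act = act, Aca = act - sag_area,
       sag_area = sag_area, span = span)
}

#' Apparent yield stress from the collapse angle
#'
#' Inverts the simplified force balance `theta = asin(rho * g * L / sigma0)`
#' of the filament collapse test: `sigma0 = rho * g * L / sin(theta)` with
#' `L` half the gap distance between pillars. "Apparent" because the model
#' treats the filament as a line load and ignores its actual volume.
#'
#' @param theta_deg measured deflection angle (degrees), in `(0, 90]`.
#' @param m a [material_params].
#' @param half_gap half the pillar gap distance `L` (mm).
#' @return Apparent yield stress (Pa).
#' @export
apparent_yield_stress <- function(theta_deg, m = material_params(), half_gap) {
  stop_if(!is_scalar_num(theta_deg) || theta_deg <= 0 || theta_deg > 90,
          "'theta_deg' must be in (0, 90]; an angle of ~0 means the stress is above measurable")
  assert_scalar_pos(half_gap, "half_gap")
  m$density * m$gravity * (half_gap / 1000) / sin(theta_deg * pi / 180)
}

#' Forward collapse force balance
#'
#' Predicted deflection angle for a given yield stress,
#' `theta = asin(rho * g * L / sigma0)`; the exact inverse of
#' [apparent_yield_stress()]. `NA` when the argument of `asin` exceeds 1
#' (the filament cannot be supported).
#'
#' @param sigma0 yield stress (Pa).
#' @param m a [material_params].
#' @param half_gap half gap distance (mm).
#' @return Deflection angle in degrees.
#' @export
collapse_theta <- function(sigma0, m = material_params(), half_gap) {
  assert_scalar_pos(sigma0, "sigma0")
  assert_scalar_pos(half_gap, "half_gap")
  a <- m$density * m$gravity * (half_gap / 1000) / sigma0
  if (a > 1) return(NA_real_)
  asin(a) * 180 / pi
}
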
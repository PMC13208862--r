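#' Chirped square-wave parameters
#'
#' Parameters of the frequency-modulated square wave that generates the
#' serpentine fusion-test pattern: `f(x) = A * sgn(sin(F * |x|^n))`.
#' `A` (mm) is the half-height of the serpentine, `F` the base frequency and
#' `n > 0` the chirp exponent; for `n > 1` the wave period (and hence the leg
#' spacing of the serpentine) shrinks with `|x|`, sweeping a range of line
#' spacings within a single print.
#'
#' @param amplitude half-height `A` of the square wave (mm).
#' @param base_freq base frequency `F` (1/mm^n).
#' @param chirp_rate chirp exponent `n` (dimensionless, > 0).
#' @param x_range closed interval of x (mm) covered by the pattern.
#' @param sample_step sampling step (mm) used to bracket sign changes; must
#'   be fine enough never to skip a root (checked against the analytic
#'   minimum period over `x_range`).
#' @return An object of class `chirp_params`.
#' @export
chirp_params <- function(amplitude = 10, base_freq = 0.05, chirp_rate = 2.1,
                         x_range = c(0, 30), sample_step = NULL) {
  assert_scalar_pos(amplitude, "amplitude")
  assert_scalar_pos(base_freq, "base_freq")
  assert_scalar_pos(chirp_rate, "chirp_rate")
  stop_if(length(x_range) != 2L || !all(is.finite(x_range)) || diff(x_range) <= 0,
          "'x_range' must be an increasing finite interval")
  stop_if(any(x_range < 0), "'x_range' must be non-negative (the pattern uses |x|)")
  ## minimum distance between consecutive roots of F*x^n = k*pi over x_range:
  ## the local period is pi / (F n x^(n-1)), smallest at the fast end.
  xf <- if (chirp_rate >= 1) max(x_range) else max(min(x_range), 1e-6)
  min_period <- pi / (base_freq * chirp_rate * xf^(chirp_rate - 1))
  if (is.null(sample_step)) sample_step <- max(min(0.05, min_period / 8), 1e-4)
  assert_scalar_pos(sample_step, "sample_step")
  stop_if(sample_step > min_period / 2,
          sprintf("'sample_step' (%g mm) could skip sign changes; need <= %g mm",
                  sample_step, min_period / 2))
  structure(list(amplitude = amplitude, base_freq = base_freq,
                 chirp_rate = chirp_rate, x_range = as.numeric(x_range),
                 sample_step = sample_step),
            class = "chirp_params")
}

#' Evaluate the chirped square wave
#'
#' `A * sgn(sin(F * |x|^n))`, with the boundary convention `sgn(0) := +1` so
#' the pattern starts on the `+A` rail. (A constant factor inside `sgn`, as
#' sometimes written, is mathematically inert and is not modelled.)
#'
#' @param x position(s) along the pattern (mm); must be finite.
#' @param p a [chirp_params] object.
#' @return Signed amplitude, `+A` or `-A`, vectorised over `x`.
#' @export
chirped_square_wave <- function(x, p) {
  stop_if(!is.numeric(x) || any(!is.finite(x)), "'x' must be finite numeric")
  s <- sin(p$base_freq * abs(x)^p$chirp_rate)
  p$amplitude * ifelse(s >= 0, 1, -1)
}

## Roots of sin(F x^n) in (lo, hi]: bracket on a sample grid, then bisect each
## bracket to 1e-6 mm so leg positions do not depend on the sampling step.
chirp_sign_changes <- function(p, tol = 1e-6) {
  g <- function(x) sin(p$base_freq * abs(x)^p$chirp_rate)
  xs <- seq(p$x_range[1], p$x_range[2], by = p$sample_step)
  if (xs[length(xs)] < p$x_range[2]) xs <- c(xs, p$x_range[2])
  sg <- ifelse(g(xs) >= 0, 1, -1)
  idx <- which(sg[-1] != sg[-length(sg)])
  vapply(idx, function(i) {
    lo <- xs[i]; hi <- xs[i + 1]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if ((g(mid) >= 0) == (g(lo) >= 0)) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

#' Toolpath container
#'
#' An ordered planar polyline with per-segment extrusion metadata: the
#' commanded geometry of a print. Stored as a vertex table where row `i > 1`
#' describes the segment from vertex `i - 1` to vertex `i` (`extrude` flag and
#' commanded line `width`); row 1 is the start point. `layer` is the 1-based
#' layer index.
#'
#' @param vertices data.frame with columns `x`, `y` (mm), `layer` (integer),
#'   `extrude` (logical; `NA` for the first vertex) and `width` (mm; `NA` on
#'   travel segments).
#' @param pattern character tag of the generating pattern.
#' @param params the generating parameter object.
#' @param meta further metadata (leg positions, gap intervals, ...).
#' @return An object of class `toolpath`.
#' @export
toolpath <- function(vertices, pattern = "custom", params = NULL, meta = list()) {
  stop_if(!is.data.frame(vertices) || nrow(vertices) < 2L,
          "a toolpath needs at least 2 vertices")
  need <- c("x", "y", "layer", "extrude", "width")
  stop_if(!all(need %in% names(vertices)),
          "vertex table needs columns x, y, layer, extrude, width")
  seg <- vertices[-1L, ]
  len <- sqrt(diff(vertices$x)^2 + diff(vertices$y)^2)
  same_layer <- diff(vertices$layer) == 0
  stop_if(any(len[same_layer] == 0), "zero-length segment in toolpath")
  stop_if(any(seg$extrude & (is.na(seg$width) | seg$width <= 0)),
          "extrude segments must carry a commanded width > 0")
  structure(list(vertices = vertices, pattern = pattern,
                 params = params, meta = meta),
            class = "toolpath")
}

#' @export
print.toolpath <- function(x, ...) {
  s <- toolpath_segments(x)
  cat(sprintf("<toolpath:%s> %d vertices, %d layers, extruded length %.2f mm\n",
              x$pattern, nrow(x$vertices), length(unique(x$vertices$layer)),
              sum(s$length[s$extrude])))
  invisible(x)
}

#' Segment table of a toolpath
#'
#' @param t a [toolpath].
#' @return data.frame with one row per segment: endpoints, layer, `extrude`,
#'   `width` and `length` (mm).
#' @export
toolpath_segments <- function(t) {
  v <- t$vertices
  n <- nrow(v)
  d <- data.frame(x0 = v$x[-n], y0 = v$y[-n], x1 = v$x[-1], y1 = v$y[-1],
                  layer = v$layer[-1], extrude = v$extrude[-1],
                  width = v$width[-1])
  d$length <- sqrt((d$x1 - d$x0)^2 + (d$y1 - d$y0)^2)
  ## drop layer-change pseudo segments of zero length
  d[!(d$length == 0 & !d$extrude), , drop = FALSE]
}

#' Export toolpath vertices as CSV
#'
#' @param t a [toolpath].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_toolpath_csv <- function(t, path) {
  utils::write.csv(t$vertices, path, row.names = FALSE)
  invisible(path)
}

#' Serpentine (filament fusion) toolpath
#'
#' Builds the frequency-modulated serpentine: vertical legs of height `2A`
#' placed at each sign change of the inner sinusoid, joined by horizontal runs
#' alternating between the `+A` and `-A` rails. For `chirp_rate > 1` the leg
#' spacings decrease strictly with `x`, sweeping the line-spacing axis of the
#' fusion test in a single continuous path. Leg positions and spacings are
#' attached as metadata for downstream fusion analysis.
#'
#' @param p a [chirp_params].
#' @param width commanded line width (mm), typically the nozzle inner
#'   diameter.
#' @return A [toolpath] with `meta$leg_x` (leg positions, mm) and
#'   `meta$spacing` (successive leg spacings `ls`, mm).
#' @export
serpentine_toolpath <- function(p, width = 0.41) {
  stop_if(!inherits(p, "chirp_params"), "'p' must be chirp_params")
  assert_scalar_pos(width, "width")
  legs <- chirp_sign_changes(p)
  stop_if(length(legs) < 2L,
          "degenerate pattern: x_range produces fewer than 2 sign changes")
  A <- p$amplitude
  ## start on the rail given by the wave value at x_range[1]
  rail <- chirped_square_wave(p$x_range[1], p) / A
  xs <- c(p$x_range[1], legs, p$x_range[2])
  vx <- numeric(0); vy <- numeric(0)
  y <- A * rail
  for (i in seq_along(xs)) {
    vx <- c(vx, xs[i]); vy <- c(vy, y)        # arrive at top/bottom of leg
    if (i > 1 && i < length(xs)) {
      y <- -y
      vx <- c(vx, xs[i]); vy <- c(vy, y)      # descend/ascend the leg
    }
  }
  v <- data.frame(x = vx, y = vy, layer = 1L,
                  extrude = c(NA, rep(TRUE, length(vx) - 1L)),
                  width = c(NA, rep(width, length(vx) - 1L)))
  toolpath(v, pattern = "serpentine", params = p,
           meta = list(leg_x = legs, spacing = diff(legs),
                       amplitude = A, commanded_width = width))
}

#' Grid pattern parameters
#'
#' @param outer_size side length of the square grid (mm); must be an integer
#'   multiple of `pore_pitch`.
#' @param pore_pitch centre-to-centre strand spacing (mm).
#' @param n_layers number of stacked layers (>= 1).
#' @param layer_height layer height (mm).
#' @param commanded_line_width commanded strand width (mm).
#' @return An object of class `grid_params`.
#' @export
grid_params <- function(outer_size = 30, pore_pitch = 5, n_layers = 2L,
                        layer_height = 0.51, commanded_line_width = 0.41) {
  assert_scalar_pos(outer_size, "outer_size")
  assert_scalar_pos(pore_pitch, "pore_pitch")
  stop_if(pore_pitch > outer_size, "'pore_pitch' cannot exceed 'outer_size'")
  k <- outer_size / pore_pitch
  stop_if(abs(k - round(k)) > 1e-9, "'outer_size' must be a multiple of 'pore_pitch'")
  stop_if(!is_scalar_num(n_layers) || n_layers < 1, "'n_layers' must be >= 1")
  assert_scalar_pos(layer_height, "layer_height")
  assert_scalar_pos(commanded_line_width, "commanded_line_width")
  structure(list(outer_size = outer_size, pore_pitch = pore_pitch,
                 n_layers = as.integer(n_layers), layer_height = layer_height,
                 commanded_line_width = commanded_line_width),
            class = "grid_params")
}

#' Grid (lattice) toolpath
#'
#' Per layer, `outer_size/pore_pitch + 1` longitudinal plus the same number of
#' transverse extrude lines spanning the full outer size (boundary lines
#' included), enclosing `(outer_size/pore_pitch)^2` square pores. Lines
#' alternate direction; orthogonal sets and successive layers are connected by
#' travel moves.
#'
#' @param p a [grid_params].
#' @return A [toolpath]; `meta$n_lines_per_layer`, `meta$n_pores` and
#'   `meta$layer_height` record the construction.
#' @export
grid_toolpath <- function(p) {
  stop_if(!inherits(p, "grid_params"), "'p' must be grid_params")
  L <- p$outer_size
  pos <- seq(0, L, by = p$pore_pitch)
  w <- p$commanded_line_width
  one_set <- function(transverse, layer) {
    out <- NULL
    for (i in seq_along(pos)) {
      a <- if (i %% 2 == 1) c(0, L) else c(L, 0)     # alternate direction
      if (!transverse) {
        seg <- data.frame(x = a, y = pos[i], layer = layer,
                          extrude = c(FALSE, TRUE), width = c(NA, w))
      } else {
        seg <- data.frame(x = pos[i], y = a, layer = layer,
                          extrude = c(FALSE, TRUE), width = c(NA, w))
      }
      out <- rbind(out, seg)
    }
    out
  }
  v <- NULL
  for (layer in seq_len(p$n_layers))
    v <- rbind(v, one_set(FALSE, layer), one_set(TRUE, layer))
  v$extrude[1] <- NA; v$width[1] <- NA
  toolpath(v, pattern = "grid", params = p,
           meta = list(n_lines_per_layer = 2L * length(pos),
                       n_pores = (length(pos) - 1L)^2,
                       line_positions = pos,
                       layer_height = p$layer_height,
                       commanded_width = w))
}

#' Collapse-test fixture geometry
#'
#' Pillars separated by known, typically doubling, gap distances; a filament
#' printed across them sags into the gaps according to its yield stress.
#' The paper's fixture spans gaps from 1 to 16 mm; pillar width and height are
#' fixture defaults needed only for rendering.
#'
#' @param gap_list gap distances (mm), strictly increasing.
#' @param pillar_width pillar top width (mm).
#' @param pillar_height pillar height (mm).
#' @return An object of class `collapse_fixture`.
#' @export
collapse_fixture <- function(gap_list = c(1, 2, 4, 8, 16),
                             pillar_width = 2, pillar_height = 10) {
  stop_if(length(gap_list) < 1L, "'gap_list' must not be empty")
  stop_if(any(gap_list < 0), "gaps must be non-negative")
  stop_if(is.unsorted(gap_list, strictly = TRUE), "gaps must be strictly increasing")
  assert_scalar_pos(pillar_width, "pillar_width")
  assert_scalar_pos(pillar_height, "pillar_height")
  structure(list(gap_list = as.numeric(gap_list), pillar_width = pillar_width,
                 pillar_height = pillar_height,
                 degenerate = any(gap_list == 0)),
            class = "collapse_fixture")
}

#' Collapse-test toolpath
#'
#' A single straight extrude line crossing every pillar and gap of the
#' fixture. The gap intervals (world x of each gap's start and end) are
#' recorded in metadata for downstream deflection-angle measurement.
#'
#' @param f a [collapse_fixture].
#' @param width commanded line width (mm).
#' @return A [toolpath] with `meta$gap_intervals` (data.frame `gap`, `x0`,
#'   `x1`) and `meta$degenerate` flagging any zero-width gap.
#' @export
collapse_toolpath <- function(f, width = 0.41) {
  stop_if(!inherits(f, "collapse_fixture"), "'f' must be collapse_fixture")
  pw <- f$pillar_width
  x <- pw
  gaps <- data.frame(gap = f$gap_list, x0 = NA_real_, x1 = NA_real_)
  for (i in seq_along(f$gap_list)) {
    gaps$x0[i] <- x
    x <- x + f$gap_list[i]
    gaps$x1[i] <- x
    x <- x + pw
  }
  total <- x
  v <- data.frame(x = c(0, total), y = 0, layer = 1L,
                  extrude = c(NA, TRUE), width = c(NA, width))
  toolpath(v, pattern = "collapse", params = f,
           meta = list(gap_intervals = gaps, total_length = total,
                       degenerate = f$degenerate, commanded_width = width))
}

#' Straight-line test toolpath
#'
#' A single straight extruded filament, the geometry of the line tests behind
#' the spreading and uniformity ratios. A small off-axis `angle` is allowed
#' (and used by the benchmark line test) so that rendered strand boundaries
#' sweep sub-pixel phases rather than locking to the raster.
#'
#' @param length line length (mm).
#' @param width commanded line width (mm).
#' @param angle inclination from the x axis (degrees).
#' @return A [toolpath].
#' @export
line_toolpath <- function(length = 30, width = 0.41, angle = 0) {
  assert_scalar_pos(length, "length")
  th <- angle * pi / 180
  v <- data.frame(x = c(0, length * cos(th)), y = c(0, length * sin(th)),
                  layer = 1L, extrude = c(NA, TRUE), width = c(NA, width))
  toolpath(v, pattern = "line", params = list(length = length, angle = angle),
           meta = list(commanded_width = width))
}
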
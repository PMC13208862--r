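#' Filament fusion analysis of a serpentine print
#'
#' Evaluates each gap of a rendered/photographed serpentine against the
#' commanded leg geometry: a gap is *open* when a single background-connected
#' corridor spans at least `coverage_threshold` (default 90%) of the leg
#' length between the two adjacent legs -- robust to single-pixel bridges
#' from noise -- and closed (fused) otherwise. The minimum line spacing
#' `lmin` is the smallest commanded spacing among open gaps, i.e. the final
#' completely open gap before the onset of coalescence. The line thickness
#' `lt` is the mean measured width over all legs, sampled per row as the
#' foreground run containing the commanded leg position, excluding a 5%
#' margin at the leg ends; rows where the leg is missing are flagged as
#' discontinuities.
#'
#' @param mask a [binary_mask] with ink as foreground.
#' @param t the generating serpentine [toolpath] (its `meta` supplies leg
#'   positions, spacings and amplitude); alternatively pass `leg_x` and
#'   `amplitude` explicitly.
#' @param leg_x,amplitude commanded leg x positions (mm) and serpentine
#'   half-height (mm); defaults from `t`.
#' @param coverage_threshold fraction of the leg length a background
#'   corridor must span for the gap to count as open.
#' @param end_margin fraction of the leg length excluded at each end (keeps
#'   the connecting runs at the +/-A rails out of both the corridor check
#'   and the width measurement).
#' @return list of class `fusion_result`: `gaps` (data.frame `ls`, `open`,
#'   `coverage`), `lmin` (mm, `NA` if no gap is open), `lt`, `lt_sd` (mm),
#'   `leg_widths` (per-leg mean widths), `broken_legs` (legs with missing
#'   rows).
#' @export
fusion_analysis <- function(mask, t = NULL, leg_x = t$meta$leg_x,
                            amplitude = t$meta$amplitude,
                            coverage_threshold = 0.9, end_margin = 0.08) {
  stop_if(!inherits(mask, "binary_mask"), "'mask' must be a binary_mask")
  stop_if(is.null(leg_x) || length(leg_x) < 2L,
          "need commanded leg positions (a serpentine toolpath or 'leg_x')")
  stop_if(is.null(amplitude), "need the serpentine amplitude")
  stop_if(coverage_threshold <= 0 || coverage_threshold > 1,
          "'coverage_threshold' must be in (0, 1]")
  sc <- mask$scale
  m <- mask$mask
  col_of <- function(x) round(world_to_px(x, mask$origin[1], sc))
  row_of <- function(y) round(world_to_px(y, mask$origin[2], sc))
  ## leg rows: central part of the legs, clear of the +/-A connector runs
  r0 <- row_of(-amplitude + end_margin * 2 * amplitude)
  r1 <- row_of(+amplitude - end_margin * 2 * amplitude)
  r0 <- max(1L, min(r0, r1)); r1 <- min(nrow(m), max(r0, r1))
  rows <- r0:r1

  ## per-leg width: run length of the foreground run containing the leg
  spacings <- diff(leg_x)
  half_win <- pmin(c(spacings[1], pmin(spacings[-length(spacings)],
                                       spacings[-1]) , spacings[length(spacings)]) / 2,
                   2)[seq_along(leg_x)]
  leg_widths <- numeric(length(leg_x))
  leg_sds <- numeric(length(leg_x))
  broken <- logical(length(leg_x))
  for (k in seq_along(leg_x)) {
    jc <- col_of(leg_x[k])
    j0 <- max(1L, col_of(leg_x[k] - half_win[k]))
    j1 <- min(ncol(m), col_of(leg_x[k] + half_win[k]))
    w <- vapply(rows, function(r) {
      if (jc < 1L || jc > ncol(m) || !m[r, jc]) return(NA_real_)
      le <- jc; ri <- jc
      while (le > j0 && m[r, le - 1L]) le <- le - 1L
      while (ri < j1 && m[r, ri + 1L]) ri <- ri + 1L
      (ri - le + 1L) / sc
    }, numeric(1))
    broken[k] <- anyNA(w)
    leg_widths[k] <- mean(w, na.rm = TRUE)
    leg_sds[k] <- stats::sd(w, na.rm = TRUE)
  }

  ## per-gap corridor: largest 4-connected background component between the
  ## commanded leg centres, measured by the fraction of leg rows it covers
  gaps <- data.frame(ls = spacings, open = NA, coverage = NA_real_)
  for (k in seq_along(spacings)) {
    j0 <- col_of(leg_x[k]); j1 <- col_of(leg_x[k + 1L])
    if (j1 - j0 < 2L) { gaps$open[k] <- FALSE; gaps$coverage[k] <- 0; next }
    strip <- !m[rows, (j0 + 1L):(j1 - 1L), drop = FALSE]
    if (!any(strip)) { gaps$open[k] <- FALSE; gaps$coverage[k] <- 0; next }
    lab <- label_matrix(strip, 4L)
    cov <- 0
    for (id in seq_len(max(lab))) {
      rows_cov <- length(unique(((which(lab == id) - 1L) %% nrow(strip)) + 1L))
      cov <- max(cov, rows_cov / nrow(strip))
    }
    gaps$coverage[k] <- cov
    gaps$open[k] <- cov >= coverage_threshold
  }

  open_ls <- gaps$ls[gaps$open]
  structure(list(gaps = gaps,
                 lmin = if (length(open_ls)) min(open_ls) else NA_real_,
                 lt = mean(leg_widths, na.rm = TRUE),
                 lt_sd = stats::sd(leg_widths, na.rm = TRUE),
                 leg_widths = leg_widths, broken_legs = which(broken)),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("<fusion_result> %d gaps (%d open), lmin = %.3g mm, lt = %.3g mm\n",
              nrow(x$gaps), sum(x$gaps$open), x$lmin, x$lt))
  invisible(x)
}
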
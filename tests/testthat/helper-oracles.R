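## Test fixtures are built in code; the oracles here are deliberately naive
## and independent of the package's implementation paths.

## Rasterize a disk of radius r_mm into a mask at `scale` px/mm.
raster_disk <- function(r_mm, scale, pad_mm = 0.5) {
  n <- ceiling((2 * r_mm + 2 * pad_mm) * scale)
  ctr <- (n + 1) / 2
  xs <- seq_len(n)
  d2 <- outer((xs - ctr)^2, (xs - ctr)^2, "+")
  binary_mask(d2 <= (r_mm * scale)^2, scale = scale)
}

## Rasterize an axis-aligned rectangle (w_mm x h_mm).
raster_rect <- function(w_mm, h_mm, scale, pad_mm = 0.5) {
  nc <- ceiling((w_mm + 2 * pad_mm) * scale)
  nr <- ceiling((h_mm + 2 * pad_mm) * scale)
  m <- matrix(FALSE, nr, nc)
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  cols <- abs(seq_len(nc) - cx) <= w_mm * scale / 2
  rows <- abs(seq_len(nr) - cy) <= h_mm * scale / 2
  m[rows, cols] <- TRUE
  binary_mask(m, scale = scale)
}

## Rasterize a rectangle rotated by `angle_deg` about its centre.
raster_rot_rect <- function(w_mm, h_mm, angle_deg, scale, pad_mm = 1) {
  ext <- (w_mm + h_mm) / sqrt(2) + 2 * pad_mm
  n <- ceiling(ext * scale)
  ctr <- (n + 1) / 2
  th <- angle_deg * pi / 180
  xs <- (seq_len(n) - ctr) / scale
  u <- outer(sin(th) * xs, cos(th) * xs, "+")     # along-axis coord
  v <- outer(cos(th) * xs, -sin(th) * xs, "+")    # cross-axis coord
  binary_mask(abs(u) <= w_mm / 2 & abs(v) <= h_mm / 2, scale = scale)
}

## Brute-force flood-fill connected-component labelling (stack-based).
flood_fill_label <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nbr <- if (connectivity == 8L)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j)); lab[i, j] <- cur
    while (length(stack) > 0L) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nbr))) {
        r <- p[1] + nbr[k, 1]; c <- p[2] + nbr[k, 2]
        if (r >= 1L && r <= nr && c >= 1L && c <= nc &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

## Exhaustive Otsu: scan all 256 thresholds, maximise between-class variance.
otsu_exhaustive <- function(px) {
  h <- tabulate(floor(px) + 1L, nbins = 256L)
  p <- h / sum(h)
  best <- -Inf; bt <- NA
  mu_t <- sum((0:255) * p)
  for (t in 0:254) {
    w0 <- sum(p[1:(t + 1)])
    if (w0 <= 0 || w0 >= 1) next
    mu0 <- sum((0:t) * p[1:(t + 1)]) / w0
    mu1 <- (mu_t - w0 * mu0) / (1 - w0)
    v <- w0 * (1 - w0) * (mu0 - mu1)^2
    if (v > best) { best <- v; bt <- t }
  }
  bt
}

## Canonical form of a label matrix: relabel by first occurrence in
## column-major order, so two labelings can be compared as partitions.
canon_labels <- function(lab) {
  ids <- unique(lab[lab > 0L])
  remap <- integer(max(ids))
  remap[ids] <- seq_along(ids)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

## Small benchmark config used by the pipeline tests.
mini_config <- function(seed = 7L, out_dir = tempfile("bq_mini_")) {
  benchmark_config(
    samples = list(
      list(name = "GridMiniP", pattern = "grid", system = "pneumatic",
           outer_size = 10, pore_pitch = 5, n_layers = 1L),
      list(name = "GridMini70S", pattern = "grid", system = "screw",
           extrusion_factor = 0.7, outer_size = 10, pore_pitch = 5,
           n_layers = 1L),
      list(name = "LineMini100S", pattern = "line", system = "screw",
           extrusion_factor = 1, length = 12),
      list(name = "CollapseMini100S", pattern = "collapse", system = "screw",
           extrusion_factor = 1, span = 16, theta_deg = 21.5)),
    seed = seed, scale = 15, out_dir = out_dir, replicates = 1L)
}
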
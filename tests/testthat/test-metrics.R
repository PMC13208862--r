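test_that("line width is the cross-sectional run length in mm", {
  ## 9 px wide vertical bar at 20 px/mm -> 0.45 mm
  m <- matrix(FALSE, 60, 30)
  m[5:55, 11:19] <- TRUE
  wm <- measure_line_width(binary_mask(m, scale = 20))
  expect_equal(wm$mean_width, 0.45, tolerance = 1e-9)
  expect_equal(wm$width_sd, 0)
  expect_equal(wm$n_broken, 0L)
})

test_that("width measurement is rotation-invariant via the principal axis", {
  w0 <- measure_line_width(raster_rot_rect(12, 0.45, 0, scale = 20))$mean_width
  w45 <- measure_line_width(raster_rot_rect(12, 0.45, 45, scale = 20))$mean_width
  expect_lt(abs(w45 - w0), 0.03 * w0)
  expect_lt(abs(w45 - 0.45), 0.03 * 0.45)
})

test_that("broken filaments are flagged and excluded", {
  m <- matrix(FALSE, 20, 200)
  m[8:12, 10:80] <- TRUE
  m[8:12, 100:190] <- TRUE          # gap from columns 81-99
  wm <- measure_line_width(binary_mask(m, scale = 20), axis = "x")
  expect_gt(wm$n_broken, 0L)
  expect_equal(wm$mean_width, 0.25, tolerance = 1e-9)
  expect_error(measure_line_width(binary_mask(matrix(FALSE, 5, 5), 20)),
               "empty")
})

test_that("spreading ratio is width over nozzle diameter", {
  nz <- nozzle_spec("22G", 0.41)
  expect_equal(spreading_ratio(0.41, nz), 1)          # ideal fidelity
  expect_equal(spreading_ratio(0.747, nz), 1.82, tolerance = 0.005)
  expect_equal(spreading_ratio(0.447, nz), 1.09, tolerance = 0.005)
  expect_error(spreading_ratio(-1, nz), "positive")
})

test_that("a perfect rectangle has uniformity ratio 1", {
  m <- matrix(FALSE, 40, 600)
  m[15:26, ] <- TRUE
  uf <- uniformity_ratio(binary_mask(m, scale = 20))
  expect_equal(uf$UF, 1, tolerance = 0.01)
  expect_equal(uf$p_th, 2 * uf$segment_length + 2 * uf$mean_width)
})

test_that("uniformity tracks a quadrature oracle on a sinusoidal boundary", {
  ## both edges displaced by a*sin(2*pi*x/lambda): amplitude 0.05 mm,
  ## wavelength 2 mm, on a 30 mm line of width 0.8 mm at 40 px/mm
  sc <- 40; a <- 0.05; lam <- 2; w <- 0.8; L <- 30
  nc <- L * sc; nr <- ceiling(3 * sc)
  xs <- (seq_len(nc) - 0.5) / sc
  ys <- (seq_len(nr) - 0.5) / sc
  y0 <- 1.5
  half <- w / 2 + a * sin(2 * pi * xs / lam)
  m <- outer(ys, seq_len(nc), function(y, j) abs(y - y0) <= half[j])
  uf <- uniformity_ratio(binary_mask(m, scale = sc))
  expect_gt(uf$UF, 1)
  ## oracle: arc length of the known boundary over the clipped window
  x0 <- min(xs) + 0.05 * (L - 1 / sc); x1 <- max(xs) - 0.05 * (L - 1 / sc)
  arc <- stats::integrate(function(x)
    sqrt(1 + (a * 2 * pi / lam * cos(2 * pi * x / lam))^2), x0, x1,
    subdivisions = 2000L)$value
  wbar <- w + 2 * a * mean(sin(2 * pi * seq(x0, x1, by = 1e-3) / lam))
  uf_true <- (2 * arc + 2 * wbar) / (2 * (x1 - x0) + 2 * wbar)
  expect_equal(uf$UF, uf_true, tolerance = 0.02)
})

test_that("multiple regions in the uniformity window are rejected", {
  m <- matrix(FALSE, 40, 200)
  m[5:10, 20:180] <- TRUE
  m[25:30, 20:180] <- TRUE
  expect_error(uniformity_ratio(binary_mask(m, scale = 20)), "one filament")
})

test_that("printability index follows its defining ratio", {
  rec <- data.frame(area = c(4, 9), perimeter = c(8, 12))
  expect_equal(printability_index(rec), c(1, 1))        # squares
  expect_equal(printability_index(2 * pi * 3, area = pi * 9), pi / 4)
  expect_equal(printability_index(6 * 2, area = 2 * 4), 36 / 32) # 2:1 rect
  expect_error(printability_index(0, area = 1), "positive")
})

test_that("pneumatic-like roughness lands near the study's uniformity", {
  tp <- line_toolpath(30, width = 0.41, angle = 2)
  img <- render_topview(tp, deposition_preset("pneumatic", seed = 7L),
                        scale = 40)
  lm <- line_metrics(binarize(img, "otsu", polarity = "dark"))
  expect_equal(lm$UF, 1.04, tolerance = 0.02)
  expect_equal(lm$SR, 1.82, tolerance = 0.03)
})
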
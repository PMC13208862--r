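test_that("rendering is deterministic for a fixed seed", {
  tp <- line_toolpath(10, width = 0.41, angle = 2)
  m <- deposition_model(spread_ratio = 1.3, roughness_amplitude = 0.05,
                        seed = 99L)
  a <- render_topview(tp, m, scale = 20)
  b <- render_topview(tp, m, scale = 20)
  expect_identical(a$pixels, b$pixels)
  an <- apply_camera_noise(a, 0.15, 4, seed = 5L)
  bn <- apply_camera_noise(b, 0.15, 4, seed = 5L)
  expect_identical(an$pixels, bn$pixels)
  expect_false(identical(an$pixels,
                         apply_camera_noise(a, 0.15, 4, seed = 6L)$pixels))
})

test_that("rendered width equals commanded x spread_ratio", {
  tp <- line_toolpath(20, width = 0.41, angle = 2)
  for (sr in c(1, 1.85)) {
    img <- render_topview(tp, deposition_model(spread_ratio = sr), scale = 40)
    mask <- binarize(img, "otsu", polarity = "dark")
    w <- measure_line_width(mask)$mean_width
    expect_equal(w, 0.41 * sr, tolerance = 1 / 40)   # within 1 px
  }
  ## the paper-scale case: 1.85 spread on a 0.41 mm command is a 0.76 mm strand
  img <- render_topview(tp, deposition_model(spread_ratio = 1.85), scale = 40)
  w <- measure_line_width(binarize(img, "otsu", polarity = "dark"))$mean_width
  expect_equal(w, 0.76, tolerance = 0.02)
})

test_that("under-resolved strands are rejected", {
  tp <- line_toolpath(10, width = 0.05)
  expect_error(render_topview(tp, deposition_model(), scale = 20),
               "under-resolved")
  expect_error(render_topview(tp, deposition_model(), scale = 5), ">= 10")
})

test_that("ink area is conserved for disjoint strands", {
  ## three disjoint parallel strands, no fusion, no roughness, no noise
  v <- data.frame(x = c(0, 20, 0, 20, 0, 20),
                  y = rep(c(0, 3, 6), each = 2),
                  layer = 1L,
                  extrude = c(NA, TRUE, FALSE, TRUE, FALSE, TRUE),
                  width = c(NA, 0.5, NA, 0.8, NA, 0.41))
  tp <- toolpath(v)
  img <- render_topview(tp, deposition_model(spread_ratio = 1.2), scale = 20)
  dark <- sum(img$pixels < 128) / 20^2
  expect_equal(dark, 20 * 1.2 * (0.5 + 0.8 + 0.41), tolerance = 0.03 * dark)
})

test_that("strands merge exactly when their edge gap is within fusion_gap", {
  two_lines <- function(gap_mm, width = 0.5) {
    ## centre distance = width + edge gap
    v <- data.frame(x = c(0, 15, 0, 15), y = rep(c(0, width + gap_mm), each = 2),
                    layer = 1L, extrude = c(NA, TRUE, FALSE, TRUE),
                    width = c(NA, width, NA, width))
    toolpath(v)
  }
  for (fg in c(0, 0.3)) {
    m <- deposition_model(fusion_gap = fg)
    for (gap in c(0.15, 0.6)) {
      img <- render_topview(two_lines(gap), m, scale = 20)
      mask <- binarize(img, "otsu", polarity = "dark")
      n <- max(bioprintqc:::label_matrix(mask$mask, 8L))
      expect_equal(n, if (gap > fg) 2L else 1L,
                   info = sprintf("gap %.2f fusion_gap %.2f", gap, fg))
    }
  }
})

test_that("boundary roughness leaves the mean width unchanged", {
  tp <- line_toolpath(25, width = 0.41, angle = 2)
  m0 <- measure_line_width(binarize(render_topview(
    tp, deposition_model(spread_ratio = 1.5), scale = 40), "otsu",
    polarity = "dark"))
  m1 <- measure_line_width(binarize(render_topview(
    tp, deposition_model(spread_ratio = 1.5, roughness_amplitude = 0.05,
                         seed = 2L), scale = 40), "otsu", polarity = "dark"))
  expect_equal(m1$mean_width, m0$mean_width, tolerance = 0.02)
  expect_gt(m1$width_sd, m0$width_sd)
})

test_that("side views encode the parabolic sag geometry", {
  s <- sag_model(span = 32, max_sag = 3.151, filament_thickness = 0.8)
  expect_equal(s$support_slope, 4 * 3.151 / 32)   # parabolic identity
  img <- render_sideview(s, scale = 20)
  expect_equal(img$meta$support_x, c(0, 32))
  ## flat filament renders a horizontal band
  s0 <- sag_model(span = 16, max_sag = 0, filament_thickness = 0.8)
  img0 <- render_sideview(s0, scale = 20)
  mask0 <- binarize(img0, "otsu", polarity = "dark")
  expect_equal(collapse_angle(mask0, img0$meta$support_x)$theta_deg, 0,
               tolerance = 1e-6)
  expect_error(sag_model(span = 16, max_sag = 20, filament_thickness = 0.8),
               "pillar height")
  expect_error(render_sideview(s, scale = 2), "3 px")
})

test_that("camera noise model matches its stated construction", {
  flat <- raster_image(matrix(128, 200, 300), scale = 10)
  ## identity at zero gradient and zero sd
  expect_identical(apply_camera_noise(flat, 0, 0)$pixels, flat$pixels)
  ## sd 5 is recovered from > 10^5 pixels within 10%
  noisy <- apply_camera_noise(flat, 0, 5, seed = 8L)
  expect_equal(sd(noisy$pixels), 5, tolerance = 0.1 * 5)
  ## gradient 0.2: left/right mean intensity ratio ~ 1.2
  grad <- apply_camera_noise(flat, 0.2, 0)
  ratio <- mean(grad$pixels[, 1]) / mean(grad$pixels[, 300])
  expect_equal(ratio, 1.2, tolerance = 0.01)
  expect_error(apply_camera_noise(flat, 1.2, 0), "illum_gradient")
})

test_that("porosity falls strictly as the spread ratio grows", {
  tp <- grid_toolpath(grid_params(outer_size = 10, pore_pitch = 5,
                                  n_layers = 1L))
  por <- vapply(c(1, 1.3, 1.6, 1.9), function(sr) {
    img <- render_topview(tp, deposition_model(spread_ratio = sr), scale = 20)
    porosity(binarize(img, "otsu", polarity = "bright"),
             roi = c(0, 10, 0, 10))
  }, numeric(1))
  expect_true(all(diff(por) < 0))
})

test_that("images and sidecars round-trip through disk", {
  tp <- line_toolpath(5, width = 0.41)
  img <- render_topview(tp, deposition_model(), scale = 20)
  for (ext in c(".png", ".tif")) {
    f <- tempfile(fileext = ext)
    write_raster(img, f)
    back <- read_raster(f)
    expect_equal(back$pixels, img$pixels)
    expect_equal(back$scale, img$scale)
    expect_equal(back$origin, img$origin)
  }
})
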
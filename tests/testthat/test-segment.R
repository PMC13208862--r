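test_that("grayscale conversion is luminance-weighted and idempotent", {
  g <- raster_image(matrix(c(0, 128, 255, 17), 2, 2), scale = 10)
  expect_identical(to_grayscale(g), g)
  rgb <- array(0, c(4, 4, 3))
  rgb[, , 1] <- 90; rgb[, , 2] <- 90; rgb[, , 3] <- 90
  expect_true(all(to_grayscale(rgb, scale = 10)$pixels == 90))
  red <- array(0, c(2, 2, 3)); red[, , 1] <- 255
  blue <- array(0, c(2, 2, 3)); blue[, , 3] <- 255
  expect_true(to_grayscale(red, scale = 10)$pixels[1] !=
                to_grayscale(blue, scale = 10)$pixels[1])
  expect_error(to_grayscale(array(0, c(2, 2, 2)), scale = 10), "channel")
})

test_that("fixed thresholding selects the bright side exactly", {
  px <- matrix(c(50, 200, 50, 200, 50, 200), 2, 3)
  img <- raster_image(px, scale = 10)
  m <- binarize(img, method = "fixed", threshold = 128, polarity = "bright")
  expect_identical(m$mask, px > 128)
  expect_equal(m$provenance$value, 128)
  ## dark polarity picks the ink instead
  md <- binarize(img, method = "fixed", threshold = 128, polarity = "dark")
  expect_identical(md$mask, px < 128)
  ## all-background image gives an empty mask
  flat <- raster_image(matrix(30, 4, 4), scale = 10)
  expect_false(any(binarize(flat, "fixed", threshold = 128)$mask))
})

test_that("Otsu threshold separates a bimodal image like the exhaustive search", {
  set.seed(3)
  px <- matrix(round(pmin(pmax(c(rnorm(6000, 60, 10), rnorm(6000, 190, 10)),
                               0), 255)), 120, 100)
  img <- raster_image(px, scale = 10)
  m <- binarize(img, method = "otsu")
  thr <- m$provenance$value
  expect_gt(thr, 60); expect_lt(thr, 190)    # strictly between the modes
  expect_equal(thr, otsu_exhaustive(px), tolerance = 2)
  expect_error(binarize(raster_image(matrix(7, 3, 3), scale = 10), "otsu"),
               "constant")
})

test_that("particle filters mirror the Analyze Particles semantics", {
  m <- matrix(FALSE, 40, 40)
  m[5:20, 5:20] <- TRUE      # 16x16 px square
  m[30, 30] <- TRUE          # single-pixel speck
  m[1:3, 35:38] <- TRUE      # touches border
  rec <- label_particles(binary_mask(m, scale = 10))
  expect_equal(nrow(rec), 3L)
  ## min size 2.5 px^2 removes the speck; border exclusion the edge blob
  kept <- filter_particles(rec, particle_filter(min_area = 2.5,
                                                exclude_border = TRUE))
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$area_px, 256L)
  ## fully permissive filter is the identity
  all_kept <- filter_particles(rec, particle_filter(min_area = 0,
                                                    exclude_border = FALSE))
  expect_equal(nrow(all_kept), 3L)
  expect_error(particle_filter(circularity_range = c(0.8, 0.2)), "inverted")
  expect_error(particle_filter(circularity_range = c(0, 2)), "1.05")
  ## the published 0.00-0.10 circularity window is available as a preset
  pp <- particle_filter_preset("paper")
  expect_equal(pp$circularity_range, c(0, 0.10))
  expect_equal(nrow(filter_particles(rec, pp)), 0L)  # squares excluded
})

test_that("porosity is the foreground fraction of the field of view", {
  m <- matrix(FALSE, 40, 40)
  m[1:20, 1:20] <- TRUE
  bm <- binary_mask(m, scale = 10)
  expect_equal(porosity(bm), 25)
  expect_equal(porosity(binary_mask(matrix(FALSE, 5, 5), 10)), 0)
  expect_equal(porosity(binary_mask(matrix(TRUE, 5, 5), 10)), 100)
  ## roi in world mm: the foreground quadrant exactly
  expect_equal(porosity(bm, roi = c(0, 2, 0, 2)), 100)
  expect_error(porosity(bm, roi = c(2, 2, 0, 1)), "extent")
  expect_error(porosity(bm, roi = c(50, 60, 50, 60)), "outside")
})

test_that("a small rendered grid segments into its designed pores", {
  tp <- grid_toolpath(grid_params(outer_size = 10, pore_pitch = 5,
                                  n_layers = 1L))
  img <- render_topview(tp, deposition_model(spread_ratio = 1), scale = 20)
  mask <- binarize(img, "otsu", polarity = "bright")
  kept <- filter_particles(label_particles(mask))
  expect_equal(nrow(kept), 4L)   # (10/5)^2 pores
  ## pores are ~(5 - 0.41)^2 mm^2 squares
  expect_equal(kept$area, rep((5 - 0.41)^2, 4), tolerance = 0.02)
})
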
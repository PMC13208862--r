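test_that("chirped square wave follows its defining sign rule", {
  p <- chirp_params(amplitude = 10, base_freq = 0.05, chirp_rate = 2.1)
  ## sin(0.05 * 1^2.1) = 0.04998 > 0
  expect_identical(chirped_square_wave(1, p), 10)
  ## sgn(0) := +1 boundary convention, any parameters
  expect_identical(chirped_square_wave(0, p), 10)
  expect_identical(chirped_square_wave(0, chirp_params(amplitude = 3)), 3)
  ## agrees with direct evaluation on a vector of positions
  x <- seq(0, 30, by = 0.37)
  expect_equal(chirped_square_wave(x, p),
               10 * ifelse(sin(0.05 * x^2.1) >= 0, 1, -1))
  expect_error(chirped_square_wave(Inf, p), "finite")
  expect_error(chirped_square_wave(NA_real_, p), "finite")
})

test_that("first sign change matches an independent bisection oracle", {
  p <- chirp_params(amplitude = 10, base_freq = 0.05, chirp_rate = 2.1)
  ## oracle: bisect F * x^n - pi = 0 directly
  f <- function(x) 0.05 * x^2.1 - pi
  lo <- 1; hi <- 20
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  x1 <- bioprintqc:::chirp_sign_changes(p)[1]
  expect_equal(x1, (lo + hi) / 2, tolerance = 1e-5)
  expect_equal(x1, 7.18, tolerance = 1e-2)
})

test_that("serpentine legs sit at the sinusoid roots and spacings chirp down", {
  p <- chirp_params(amplitude = 10, base_freq = 0.05, chirp_rate = 2.1,
                    x_range = c(0, 30))
  tp <- serpentine_toolpath(p)
  ## oracle: count k with (k*pi/F)^(1/n) inside the range
  ks <- 1:1000
  roots <- (ks * pi / 0.05)^(1 / 2.1)
  expect_length(tp$meta$leg_x, sum(roots > 0 & roots <= 30))
  expect_equal(tp$meta$leg_x, roots[roots <= 30], tolerance = 1e-5)
  ## strictly decreasing spacing for chirp_rate > 1 (the figure-5 pattern)
  expect_true(all(diff(tp$meta$spacing) < 0))
  ## legs alternate between the +A and -A rails continuously
  expect_true(all(abs(tp$vertices$y) == 10))
})

test_that("unmodulated square wave gives constant leg spacing pi/F", {
  p <- chirp_params(amplitude = 5, base_freq = 0.5, chirp_rate = 1,
                    x_range = c(0, 40))
  tp <- serpentine_toolpath(p)
  expect_equal(tp$meta$spacing, rep(pi / 0.5, length(tp$meta$spacing)),
               tolerance = 1e-5)
})

test_that("leg spacing is monotone non-increasing for chirp_rate >= 1", {
  set.seed(42)
  for (i in 1:20) {
    p <- chirp_params(amplitude = runif(1, 2, 15),
                      base_freq = runif(1, 0.02, 0.6),
                      chirp_rate = runif(1, 1, 3),
                      x_range = c(0, runif(1, 20, 50)))
    tp <- tryCatch(serpentine_toolpath(p), error = function(e) NULL)
    if (is.null(tp)) next   # fewer than 2 sign changes in range
    ## non-increasing up to the 1e-6 mm bisection tolerance of leg placement
    expect_true(all(diff(tp$meta$spacing) <= 1e-5))
  }
})

test_that("degenerate serpentine ranges are rejected", {
  p <- chirp_params(base_freq = 0.05, chirp_rate = 2.1, x_range = c(0, 8))
  expect_error(serpentine_toolpath(p), "degenerate")
})

test_that("grid toolpath encloses the designed pores", {
  p <- grid_params(outer_size = 30, pore_pitch = 5, n_layers = 2L)
  tp <- grid_toolpath(p)
  expect_equal(tp$meta$n_lines_per_layer, 14L)  # 7 longitudinal + 7 transverse
  expect_equal(tp$meta$n_pores, 36L)            # (30/5 - 1 + 1 - 1)^2 cells
  seg <- toolpath_segments(tp)
  ext <- seg[seg$extrude, ]
  ## extruded length per layer: 14 lines x 30 mm
  for (l in 1:2)
    expect_equal(sum(ext$length[ext$layer == l]), 420)
  expect_setequal(unique(tp$vertices$layer), 1:2)
  expect_error(grid_params(outer_size = 4, pore_pitch = 5), "exceed")
  expect_error(grid_params(outer_size = 29, pore_pitch = 5), "multiple")
})

test_that("collapse toolpath crosses every pillar and gap", {
  f <- collapse_fixture(gap_list = c(1, 2, 4, 8, 16), pillar_width = 2)
  tp <- collapse_toolpath(f)
  ## 6 pillars of 2 mm + 31 mm of gaps
  expect_equal(tp$meta$total_length, 6 * 2 + 31)
  gi <- tp$meta$gap_intervals
  expect_equal(gi$x1 - gi$x0, c(1, 2, 4, 8, 16))
  expect_false(tp$meta$degenerate)
  ## a zero gap degenerates to a supported line and is flagged
  f0 <- collapse_fixture(gap_list = c(0, 2))
  expect_true(collapse_toolpath(f0)$meta$degenerate)
  expect_error(collapse_fixture(gap_list = numeric(0)), "empty")
  expect_error(collapse_fixture(gap_list = c(4, 2)), "increasing")
})

test_that("unit-area filament diameter is 2/sqrt(pi)", {
  d <- effective_unit_diameter()
  expect_equal(round(d, 5), 1.12838)
  expect_equal(pi * (d / 2)^2, 1, tolerance = 1e-12)   # defining identity
  expect_lt(abs(d - 1.128379167) / 1.128379167, 1e-6)
})

test_that("volumetric calibration validates its invariants", {
  cal <- volumetric_calibration()
  expect_equal(cal$cross_section_area, 1, tolerance = 1e-4)
  expect_error(volumetric_calibration(rotation_distance = -1), "positive")
  expect_error(volumetric_calibration(extrusion_factor = 0), "0, 1")
  expect_error(volumetric_calibration(extrusion_factor = 1.2), "0, 1")
})
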
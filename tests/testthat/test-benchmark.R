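test_that("benchmark runs are deterministic and byte-identical", {
  d1 <- tempfile("bq_a_"); d2 <- tempfile("bq_b_")
  r1 <- run_benchmark(mini_config(seed = 7L, out_dir = d1))
  r2 <- run_benchmark(mini_config(seed = 7L, out_dir = d2))
  expect_identical(readLines(file.path(d1, "report.csv")),
                   readLines(file.path(d2, "report.csv")))
  expect_identical(readLines(file.path(d1, "aggregates.csv")),
                   readLines(file.path(d2, "aggregates.csv")))
  expect_true(all(r1$rows$status == "ok"))

  ## every artifact referenced in the report exists on disk
  for (col in c("gcode", "image", "mask", "particles")) {
    paths <- r1$rows[[col]]
    paths <- paths[!is.na(paths)]
    expect_true(all(file.exists(file.path(d1, paths))), info = col)
  }

  ## every configured sample yields a row; removing one removes its row only
  expect_setequal(unique(r1$rows$sample),
                  c("GridMiniP", "GridMini70S", "LineMini100S",
                    "CollapseMini100S"))
  cfg3 <- mini_config(seed = 7L, out_dir = tempfile("bq_c_"))
  cfg3$samples <- cfg3$samples[-3]
  r3 <- run_benchmark(cfg3)
  expect_setequal(unique(r3$rows$sample),
                  setdiff(unique(r1$rows$sample), "LineMini100S"))
  ## untouched samples are unchanged (seeds derive from sample names)
  common <- intersect(names(r1$rows), names(r3$rows))
  expect_equal(r3$rows[r3$rows$sample == "GridMiniP", common],
               r1$rows[r1$rows$sample == "GridMiniP", common],
               ignore_attr = TRUE)
})

test_that("the mini benchmark measures what its generators encode", {
  d <- tempfile("bq_m_")
  r <- run_benchmark(mini_config(seed = 3L, out_dir = d))
  rows <- r$rows
  line <- rows[rows$sample == "LineMini100S", ]
  expect_equal(line$SR, 0.76 / 0.41, tolerance = 0.05)
  col <- rows[rows$sample == "CollapseMini100S", ]
  expect_equal(col$theta_deg, 21.5, tolerance = 0.4)
  expect_equal(col$sigma0_Pa,
               apparent_yield_stress(col$theta_deg, material_params(), 8),
               tolerance = 1e-6)
  grids <- rows[rows$pattern == "grid", ]
  ## pneumatic strands are wider: fewer open pore area
  expect_lt(grids$porosity_pct[grids$sample == "GridMiniP"],
            grids$porosity_pct[grids$sample == "GridMini70S"])
})

test_that("system comparison tables sort and baseline correctly", {
  d <- tempfile("bq_cmp_")
  r <- run_benchmark(mini_config(seed = 5L, out_dir = d))
  tab <- compare_systems(r, "porosity_pct", baseline = "GridMiniP")
  expect_equal(nrow(tab), 2L)
  expect_true(!is.unsorted(tab$value))
  expect_equal(tab$delta[tab$sample == "GridMiniP"], 0)
  expect_gt(tab$delta[tab$sample == "GridMini70S"], 0)
  expect_error(compare_systems(r, "no_such_metric"), "unknown metric")
  one <- r; one$rows <- one$rows[one$rows$sample == "GridMiniP", ]
  expect_error(compare_systems(one, "porosity_pct"), "2 samples")
})

test_that("configurations are validated before any output", {
  expect_error(benchmark_config(list()), "no samples")
  s <- list(name = "A", pattern = "grid", system = "screw",
            extrusion_factor = 0.7)
  expect_error(benchmark_config(list(s, s)), "unique")
  expect_error(benchmark_config(list(list(name = "B", pattern = "nope",
                                          system = "screw"))), "pattern")
  expect_error(benchmark_config(list(list(name = "C", pattern = "grid",
                                          system = "screw"))),
               "extrusion_factor")
  ## the full study matrix mirrors the published sample table
  cfg <- default_benchmark_config()
  nm <- vapply(cfg$samples, `[[`, character(1), "name")
  expect_true(all(c("GridP", "Grid50S", "Grid100S", "SerpentineSF50",
                    "LineP", "Collapse100S") %in% nm))
  expect_length(nm, 24L)
})

test_that("YAML configurations load through the same validation", {
  f <- system.file("extdata", "example_config.yaml", package = "bioprintqc")
  expect_true(nzchar(f))
  cfg <- read_benchmark_config(f, out_dir = tempfile())
  expect_s3_class(cfg, "benchmark_config")
  expect_equal(cfg$nozzle$inner_diameter, 0.41)
  expect_gt(length(cfg$samples), 0L)
})
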
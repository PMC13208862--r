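#' Deposition-model presets for the two extrusion systems
#'
#' Returns the deposition parameters emulating each system's filament
#' morphology, anchored to the study's measurements: strand width grows
#' linearly with the screw extruder's volumetric factor from 0.45 mm at 50%
#' to 0.76 mm at 100% (spreading ratio 1.10-1.85 over a 0.41 mm nozzle),
#' while the pneumatic system sits at a fixed spreading ratio of 1.82 with
#' rougher boundaries (uniformity ~1.04), stronger corner blobbing and a
#' larger fusion gap from pressure hysteresis.
#'
#' @param system `"screw"` or `"pneumatic"`.
#' @param extrusion_factor volumetric factor in `[0.5, 1]` (screw only).
#' @param nozzle_diameter nozzle inner diameter (mm).
#' @param seed RNG seed for the boundary roughness.
#' @return A [deposition_model].
#' @export
deposition_preset <- function(system = c("screw", "pneumatic"),
                              extrusion_factor = 1,
                              nozzle_diameter = 0.41, seed = 1L) {
  system <- match.arg(system)
  if (system == "screw") {
    stop_if(extrusion_factor < 0.5 || extrusion_factor > 1,
            "'extrusion_factor' must be in [0.5, 1]")
    w <- 0.45 + (extrusion_factor - 0.5) / 0.5 * (0.76 - 0.45)
    deposition_model(spread_ratio = w / nozzle_diameter,
                     roughness_amplitude = 0.06, roughness_wavelength = 1.5,
                     corner_round_radius = 0.10, fusion_gap = 0.05,
                     seed = seed)
  } else {
    deposition_model(spread_ratio = 1.82,
                     roughness_amplitude = 0.095, roughness_wavelength = 1.5,
                     corner_round_radius = 0.35, fusion_gap = 0.50,
                     seed = seed)
  }
}

#' Benchmark configuration
#'
#' Validates and normalises a benchmark configuration: global settings
#' (master seed, render scale, nozzle, material constants, print speed,
#' camera-noise level, particle-filter preset) plus a list of samples. Each
#' sample names a pattern (`grid`, `serpentine`, `line`, `collapse`), a
#' system (`screw`/`pneumatic`), and optionally an `extrusion_factor`,
#' `pressure_kPa`, replicate count and pattern-specific parameters.
#' All per-sample randomness is derived from the master seed and the sample
#' name, so adding or removing samples never perturbs the others.
#'
#' @param samples list of sample definitions (see
#'   [default_benchmark_config()] for the study matrix).
#' @param seed master seed.
#' @param scale render scale (px/mm).
#' @param out_dir output directory for artifacts.
#' @param nozzle a [nozzle_spec].
#' @param material a [material_params].
#' @param speed print speed (mm/s).
#' @param illum_gradient,noise_sd camera-noise settings for rendered images.
#' @param filter_preset pore filter preset name (see
#'   [particle_filter_preset()]).
#' @param replicates default replicate count per sample.
#' @return An object of class `benchmark_config`.
#' @export
benchmark_config <- function(samples, seed = 1L, scale = 20,
                             out_dir = tempfile("bioprintqc_"),
                             nozzle = nozzle_spec(),
                             material = material_params(),
                             speed = 20, illum_gradient = 0.1, noise_sd = 3,
                             filter_preset = "default", replicates = 3L) {
  stop_if(length(samples) == 0L, "config has no samples")
  nm <- vapply(samples, function(s) s$name %||% NA_character_, character(1))
  stop_if(anyNA(nm), "every sample needs a name")
  stop_if(anyDuplicated(nm) > 0L, "sample names must be unique")
  ok_pat <- c("grid", "serpentine", "line", "collapse")
  for (s in samples) {
    stop_if(is.null(s$pattern) || !s$pattern %in% ok_pat,
            sprintf("sample '%s': unknown pattern '%s'", s$name, s$pattern %||% "<missing>"))
    stop_if(is.null(s$system) || !s$system %in% c("screw", "pneumatic"),
            sprintf("sample '%s': unknown system", s$name))
    if (identical(s$system, "screw"))
      stop_if(is.null(s$extrusion_factor),
              sprintf("sample '%s': screw samples need an extrusion_factor", s$name))
  }
  structure(list(samples = samples, seed = as.integer(seed), scale = scale,
                 out_dir = out_dir, nozzle = nozzle, material = material,
                 speed = speed, illum_gradient = illum_gradient,
                 noise_sd = noise_sd, filter_preset = filter_preset,
                 replicates = as.integer(replicates)),
            class = "benchmark_config")
}

#' The study's sample matrix as a benchmark configuration
#'
#' Builds the full pneumatic-vs-screw comparison: grid prints (30 x 30 mm,
#' 5 mm pores, 2 layers at 0.51 mm) from the pneumatic system and the screw
#' system at 50-100% extrusion factor, serpentine fusion tests, straight
#' line tests, and collapse tests at 50/75/100% flow whose side views carry
#' the study's measured deflection angles as ground truth. Three replicates
#' per sample; replicates differ only in the noise seed.
#'
#' @param seed master seed.
#' @param ... overrides passed to [benchmark_config()].
#' @return A `benchmark_config`.
#' @export
default_benchmark_config <- function(seed = 1L, ...) {
  factors <- seq(0.5, 1, by = 0.1)
  samples <- list()
  add <- function(x) samples[[length(samples) + 1L]] <<- x
  add(list(name = "GridP", pattern = "grid", system = "pneumatic",
           pressure_kPa = 75))
  for (f in factors)
    add(list(name = sprintf("Grid%dS", round(100 * f)), pattern = "grid",
             system = "screw", extrusion_factor = f))
  add(list(name = "SerpentineP", pattern = "serpentine", system = "pneumatic",
           pressure_kPa = 75))
  for (f in factors)
    add(list(name = sprintf("SerpentineSF%d", round(100 * f)),
             pattern = "serpentine", system = "screw", extrusion_factor = f))
  add(list(name = "LineP", pattern = "line", system = "pneumatic",
           pressure_kPa = 75))
  for (f in factors)
    add(list(name = sprintf("Line%dS", round(100 * f)), pattern = "line",
             system = "screw", extrusion_factor = f))
  ## collapse: measured deflections at the fixed 32 mm span (sag = L tan(theta)/4)
  collapse_f <- c(0.5, 0.75, 1)
  collapse_th <- c(9.04, 14.2, 21.5)
  for (i in seq_along(collapse_f))
    add(list(name = sprintf("Collapse%dS", round(100 * collapse_f[i])),
             pattern = "collapse", system = "screw",
             extrusion_factor = collapse_f[i],
             span = 32, theta_deg = collapse_th[i]))
  benchmark_config(samples, seed = seed, ...)
}

#' Read a benchmark configuration from YAML
#'
#' Expects top-level keys mirroring the arguments of [benchmark_config()]
#' (`seed`, `scale`, `speed`, `illum_gradient`, `noise_sd`,
#' `filter_preset`, `replicates`, `nozzle: {gauge, inner_diameter}`,
#' `material: {density, gravity, reference_yield_stress}`) plus a `samples`
#' list.
#'
#' @param path YAML file path.
#' @param out_dir output directory (overrides any value in the file).
#' @return A `benchmark_config`.
#' @export
read_benchmark_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  stop_if(is.null(y$samples), "YAML config needs a 'samples' list")
  nz <- if (is.null(y$nozzle)) nozzle_spec() else
    nozzle_spec(y$nozzle$gauge %||% "22G", y$nozzle$inner_diameter %||% 0.41)
  mt <- if (is.null(y$material)) material_params() else
    material_params(y$material$density %||% 1000,
                    y$material$gravity %||% 9.81,
                    y$material$reference_yield_stress %||% 350)
  benchmark_config(y$samples, seed = y$seed %||% 1L, scale = y$scale %||% 20,
                   out_dir = out_dir %||% y$out_dir %||% tempfile("bioprintqc_"),
                   nozzle = nz, material = mt, speed = y$speed %||% 20,
                   illum_gradient = y$illum_gradient %||% 0.1,
                   noise_sd = y$noise_sd %||% 3,
                   filter_preset = y$filter_preset %||% "default",
                   replicates = y$replicates %||% 3L)
}

## One sample replicate: generate -> render -> segment -> measure.
## Returns a named list of metric values plus artifact paths.
run_sample <- function(s, cfg, rep_i) {
  seed_i <- derive_seed(cfg$seed, paste0(s$name, "#", rep_i))
  d_nozzle <- cfg$nozzle$inner_diameter
  ef <- s$extrusion_factor %||% 1
  model <- deposition_preset(s$system, ef, d_nozzle, seed = seed_i)
  row <- list(sample = s$name, replicate = rep_i, pattern = s$pattern,
              system = s$system, extrusion_factor = ef)
  tag <- sprintf("%s_rep%d", s$name, rep_i)

  if (s$pattern == "collapse") {
    span <- s$span %||% 32
    theta <- s$theta_deg
    sag <- s$sag_mm %||% (span * tan((theta %||% 0) * pi / 180) / 4)
    thick <- d_nozzle * model$spread_ratio
    sm <- sag_model(span = span, max_sag = sag, filament_thickness = thick)
    img <- render_sideview(sm, scale = cfg$scale)
    meta <- img$meta
    img <- apply_camera_noise(img, cfg$illum_gradient, cfg$noise_sd, seed_i)
    img_path <- file.path("images", paste0(tag, ".png"))
    write_raster(img, file.path(cfg$out_dir, img_path))
    mask <- binarize(img, "otsu", polarity = "dark")
    mask_path <- file.path("masks", paste0(tag, "_mask.png"))
    write_raster(mask, file.path(cfg$out_dir, mask_path))
    ca <- collapse_angle(mask, meta$support_x)
    cr <- collapse_rate(mask, meta$support_x, meta$pillar_top_y,
                        meta$floor_depth)
    row$theta_deg <- ca$theta_deg
    row$Cf_pct <- cr$Cf
    row$sigma0_Pa <- apparent_yield_stress(ca$theta_deg, cfg$material,
                                           half_gap = span / 2)
    row$image <- img_path; row$mask <- mask_path
    return(row)
  }

  tp <- switch(s$pattern,
    grid = grid_toolpath(grid_params(
      outer_size = s$outer_size %||% 30, pore_pitch = s$pore_pitch %||% 5,
      n_layers = s$n_layers %||% 2L, layer_height = s$layer_height %||% 0.51,
      commanded_line_width = d_nozzle)),
    serpentine = serpentine_toolpath(chirp_params(
      amplitude = s$amplitude %||% 10, base_freq = s$base_freq %||% 0.05,
      chirp_rate = s$chirp_rate %||% 2.1,
      x_range = c(s$x_min %||% 0, s$x_max %||% 30)), width = d_nozzle),
    line = line_toolpath(length = s$length %||% 30, width = d_nozzle,
                         angle = s$angle %||% 2))
  cal <- volumetric_calibration(extrusion_factor = ef)
  gpath <- file.path("gcode", paste0(s$name, ".gcode"))
  if (rep_i == 1L)
    write_gcode(to_gcode(tp, cal, speed = cfg$speed,
                         layer_height = tp$meta$layer_height %||% 0.51),
                file.path(cfg$out_dir, gpath))
  img <- render_topview(tp, model, scale = cfg$scale)
  img <- apply_camera_noise(img, cfg$illum_gradient, cfg$noise_sd, seed_i)
  img_path <- file.path("images", paste0(tag, ".png"))
  write_raster(img, file.path(cfg$out_dir, img_path))
  row$gcode <- gpath; row$image <- img_path

  if (s$pattern == "grid") {
    mask <- binarize(img, "otsu", polarity = "bright")
    parts <- filter_particles(label_particles(mask),
                              particle_filter_preset(cfg$filter_preset))
    w_rend <- d_nozzle * model$spread_ratio
    outer <- s$outer_size %||% 30
    roi <- c(-w_rend / 2, outer + w_rend / 2, -w_rend / 2, outer + w_rend / 2)
    row$porosity_pct <- porosity(mask, roi)
    row$n_pores <- nrow(parts)
    pr <- printability_index(parts)
    row$Pr_mean <- mean(pr); row$Pr_sd <- stats::sd(pr)
    row$hydraulic_radius_mm <- mean(parts$hydraulic_radius)
    row$pore_area_mm2 <- mean(parts$area)
    row$pore_perimeter_mm <- mean(parts$perimeter)
    ppath <- file.path("tables", paste0(tag, "_particles.csv"))
    utils::write.csv(as.data.frame(parts), file.path(cfg$out_dir, ppath),
                     row.names = FALSE)
    row$particles <- ppath
  } else if (s$pattern == "serpentine") {
    mask <- binarize(img, "otsu", polarity = "dark")
    fr <- fusion_analysis(mask, tp)
    row$lmin_mm <- fr$lmin
    row$lt_mm <- fr$lt
    row$n_open_gaps <- sum(fr$gaps$open)
  } else if (s$pattern == "line") {
    mask <- binarize(img, "otsu", polarity = "dark")
    lm <- line_metrics(mask, cfg$nozzle)
    row$mean_width_mm <- lm$mean_width
    row$width_sd_mm <- lm$width_sd
    row$SR <- lm$SR
    row$UF <- lm$UF
  }
  mask_path <- file.path("masks", paste0(tag, "_mask.png"))
  write_raster(mask, file.path(cfg$out_dir, mask_path))
  row$mask <- mask_path
  row
}

#' Run the full benchmark pipeline
#'
#' Executes generate -> render -> segment -> measure for every sample and
#' replicate of a configuration, writing G-code, images, masks and particle
#' tables under the configured output directory, plus `report.csv` (one row
#' per replicate), `aggregates.csv` (per-sample means) and `report.json`
#' (rows, aggregates and provenance). Per-sample failures are recorded as
#' failure rows and the run continues; the run is deterministic and
#' idempotent for a fixed configuration and seed.
#'
#' @param cfg a [benchmark_config].
#' @return list of class `benchmark_report`: `rows` (data.frame),
#'   `aggregates` (data.frame), `provenance` (list).
#' @export
run_benchmark <- function(cfg) {
  stop_if(!inherits(cfg, "benchmark_config"), "'cfg' must be a benchmark_config")
  for (d in file.path(cfg$out_dir, c("gcode", "images", "masks", "tables")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (s in cfg$samples) {
    n_rep <- s$replicates %||% cfg$replicates
    for (rep_i in seq_len(n_rep)) {
      res <- tryCatch(c(run_sample(s, cfg, rep_i), list(status = "ok", error = NA_character_)),
                      error = function(e) list(sample = s$name, replicate = rep_i,
                                               pattern = s$pattern, system = s$system,
                                               status = "failed",
                                               error = conditionMessage(e)))
      rows[[length(rows) + 1L]] <- res
    }
  }
  all_names <- unique(unlist(lapply(rows, names)))
  tab <- do.call(rbind, lapply(rows, function(r) {
    r[setdiff(all_names, names(r))] <- NA
    as.data.frame(r[all_names])
  }))
  num_cols <- names(tab)[vapply(tab, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, "replicate")
  agg <- stats::aggregate(tab[num_cols], by = list(sample = tab$sample),
                          FUN = function(x) mean(x, na.rm = TRUE))
  agg <- agg[match(unique(tab$sample), agg$sample), , drop = FALSE]
  prov <- list(seed = cfg$seed, scale = cfg$scale,
               filter_preset = cfg$filter_preset,
               config_hash = fnv1a32(paste(deparse(unclass(
                 cfg[setdiff(names(cfg), "out_dir")])), collapse = "")),
               package_version = as.character(utils::packageVersion("bioprintqc")))
  utils::write.csv(tab, file.path(cfg$out_dir, "report.csv"), row.names = FALSE)
  utils::write.csv(agg, file.path(cfg$out_dir, "aggregates.csv"), row.names = FALSE)
  jsonlite::write_json(list(rows = tab, aggregates = agg, provenance = prov),
                       file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  structure(list(rows = tab, aggregates = agg, provenance = prov,
                 out_dir = cfg$out_dir),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("<benchmark_report> %d rows (%d failed), %d samples, seed %d\n",
              nrow(x$rows), sum(x$rows$status == "failed"),
              length(unique(x$rows$sample)), x$provenance$seed))
  invisible(x)
}

#' Compare samples on one metric
#'
#' Per-sample means of a metric, sorted, with deltas against a named
#' baseline sample -- the roll-up used for the pneumatic-vs-screw
#' comparisons.
#'
#' @param report a `benchmark_report`.
#' @param metric metric column name in the report rows (e.g.
#'   `"porosity_pct"`, `"SR"`, `"lmin_mm"`).
#' @param baseline optional baseline sample name; deltas are
#'   `value - baseline`.
#' @param decreasing sort order.
#' @return data.frame with `sample`, `value`, `n` and (with a baseline)
#'   `delta`.
#' @export
compare_systems <- function(report, metric, baseline = NULL,
                            decreasing = FALSE) {
  stop_if(!inherits(report, "benchmark_report"), "'report' must be a benchmark_report")
  stop_if(!metric %in% names(report$rows),
          sprintf("unknown metric '%s'", metric))
  ok <- !is.na(report$rows[[metric]])
  d <- report$rows[ok, , drop = FALSE]
  stop_if(length(unique(d$sample)) < 2L,
          "need at least 2 samples with this metric")
  agg <- stats::aggregate(d[[metric]], by = list(sample = d$sample), FUN = mean)
  names(agg)[2] <- "value"
  agg$n <- as.integer(table(d$sample)[agg$sample])
  agg <- agg[order(agg$value, decreasing = decreasing), , drop = FALSE]
  if (!is.null(baseline)) {
    stop_if(!baseline %in% agg$sample, sprintf("baseline '%s' not in report", baseline))
    agg$delta <- agg$value - agg$value[agg$sample == baseline]
  }
  rownames(agg) <- NULL
  agg
}
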
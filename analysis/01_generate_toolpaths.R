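#!/usr/bin/env Rscript
## Generate the four benchmark toolpaths and their volumetrically calibrated
## G-code: the chirped serpentine (fusion test), the 30 mm grid (porosity /
## printability), the straight line test and the collapse fixture crossing.
## Writes G-code and vertex CSVs under results/toolpaths/.

suppressMessages(library(bioprintqc))
out <- "results/toolpaths"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cal <- volumetric_calibration()   # 1 E-unit = 1 mm^3, 10 mm^3/rev
cat(sprintf("unit-area filament diameter: %.5f mm\n", effective_unit_diameter()))

paths <- list(
  serpentine = serpentine_toolpath(chirp_params(amplitude = 10,
                                                base_freq = 0.05,
                                                chirp_rate = 2.1,
                                                x_range = c(0, 30))),
  grid = grid_toolpath(grid_params(outer_size = 30, pore_pitch = 5,
                                   n_layers = 2L, layer_height = 0.51)),
  line = line_toolpath(length = 30, width = 0.41),
  collapse = collapse_toolpath(collapse_fixture(gap_list = c(1, 2, 4, 8, 16))))

for (nm in names(paths)) {
  tp <- paths[[nm]]
  lh <- if (is.null(tp$meta$layer_height)) 0.41 else tp$meta$layer_height
  g <- to_gcode(tp, cal, speed = 20, layer_height = lh)
  write_gcode(g, file.path(out, paste0(nm, ".gcode")))
  write_toolpath_csv(tp, file.path(out, paste0(nm, "_vertices.csv")))
  seg <- toolpath_segments(tp)
  cat(sprintf("%-10s %3d vertices, extruded %6.1f mm, total E %7.3f mm^3\n",
              nm, nrow(tp$vertices), sum(seg$length[seg$extrude]),
              max(parse_gcode(g)$e)))
}

sp <- paths$serpentine$meta
cat("\nserpentine leg spacings (mm), largest to smallest:\n")
cat(paste(sprintf("%.2f", sp$spacing), collapse = " "), "\n")
cat(sprintf("-> the spacing sweep brackets both systems' expected fusion limits\n"))
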
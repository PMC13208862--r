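# bioprintqc

Quantitative print-quality benchmarking for extrusion bioprinting.

Extrusion bioprinting needs open, square scaffold pores and strands that
stay at the nozzle width — but print quality is still mostly judged by
eye. `bioprintqc` implements the standard printer-based benchmark suite as
a tested R pipeline, aimed at the comparison between pneumatic extrusion
and screw-driven (positive-displacement, volumetric) extrusion, where
deliberate under-extrusion can cancel viscoelastic die swell:

* **Benchmark toolpaths + G-code** — chirped serpentine (filament fusion
  test), lattice grid, straight line, and pillar-crossing collapse line,
  serialized as volumetrically calibrated G-code (the 2/√π = 1.12838 mm
  "diameter trick" makes 1 E-unit = 1 mm³).
* **Synthetic deposition renderer** — seeded top-view/side-view images
  with the failure modes the metrics detect: spreading, boundary
  roughness, strand fusion, parabolic sag, illumination gradient, sensor
  noise. It stands in for camera data, with ground truth in metadata.
* **Segmentation** — Fiji-style workflow: 8-bit grayscale, global
  threshold (fixed/Otsu), Analyze-Particles-like labelling with sub-pixel
  (marching-squares) perimeters, size/circularity/border filters.
* **Metrics** — spreading ratio SR = w/d, uniformity ratio
  UF = p_ext/p_th, printability index Pr = L²/(16A), porosity, pore
  hydraulic radius A/P, fusion line spacing (lt, ls, lmin), collapse
  angle θ and rate Cf, and the apparent yield stress
  σ₀ = ρgL/sin θ.
* **Benchmark orchestration** — `run_benchmark()` executes
  generate → render → segment → measure for a whole sample matrix from
  one seeded config (R list or YAML) and writes CSV/JSON reports;
  `compare_systems()` rolls up per-system comparisons.

## Worked example

```r
library(bioprintqc)

## a 30 x 30 mm grid with 36 designed 5 mm pores, printed faithfully
tp   <- grid_toolpath(grid_params(outer_size = 30, pore_pitch = 5,
                                  n_layers = 2, layer_height = 0.51))
img  <- render_topview(tp, deposition_model(spread_ratio = 1), scale = 20)
mask <- binarize(img, "otsu", polarity = "bright")
pores <- filter_particles(label_particles(mask))

nrow(pores)                      #> 36
mean(printability_index(pores))  #> 0.9792681  (1 = perfectly square pores)
porosity(mask, roi = c(-0.205, 30.205, -0.205, 30.205))
                                 #> 82.4446    (% open area of the scaffold)

## collapse test: a 1.273 mm sag over a 32 mm span
sv <- render_sideview(sag_model(span = 32, max_sag = 1.273,
                                filament_thickness = 0.8), scale = 20)
th <- collapse_angle(binarize(sv, "otsu", polarity = "dark"),
                     sv$meta$support_x)$theta_deg
th                               #> 8.997899  (degrees)
apparent_yield_stress(th, material_params(), half_gap = 16)
                                 #> 1003.592  (Pa; apparent yield stress)
```

The numbers mean: all 36 pores survive segmentation and filtering; their
mean printability index sits at ~0.98 (square pores); the scaffold keeps
~82.4% open area; and the shallow 9° deflection implies an apparent yield
stress near 1000 Pa — a stiff, self-supporting filament.

## Analysis workflow

The `analysis/` scripts run the full study matrix over the package:

```sh
Rscript analysis/01_generate_toolpaths.R    # toolpaths + calibrated G-code
Rscript analysis/02_run_benchmark.R         # 24 samples x 3 replicates
Rscript analysis/03_line_collapse_fusion.R  # SR/UF, theta -> sigma0, lmin/lt
Rscript analysis/04_grid_analysis.R         # porosity, Pr, hydraulic radius
```

Outputs (G-code, images, masks, particle tables, roll-up tables) land
under `results/`. The methods vignette
(`vignettes/print-quality-benchmarking.Rmd`) documents the models, the
synthetic-data generator and every numerical choice.

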
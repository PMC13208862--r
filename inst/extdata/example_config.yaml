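# Example benchmark configuration: a reduced pneumatic-vs-screw comparison.
# Units: mm, mm/s, px/mm; extrusion_factor is the fraction of theoretical
# volumetric flow commanded to the screw extruder.
seed: 1
scale: 15
speed: 20
illum_gradient: 0.1
noise_sd: 3
filter_preset: default
replicates: 1
nozzle:
  gauge: 22G
  inner_diameter: 0.41
material:
  density: 1000
  gravity: 9.81
  reference_yield_stress: 350
samples:
  - name: GridP
    pattern: grid
    system: pneumatic
    pressure_kPa: 75
    outer_size: 10
    pore_pitch: 5
    n_layers: 1
  - name: Grid70S
    pattern: grid
    system: screw
    extrusion_factor: 0.7
    outer_size: 10
    pore_pitch: 5
    n_layers: 1
  - name: Line100S
    pattern: line
    system: screw
    extrusion_factor: 1
    length: 12
  - name: Collapse100S
    pattern: collapse
    system: screw
    extrusion_factor: 1
    span: 32
    theta_deg: 21.5
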
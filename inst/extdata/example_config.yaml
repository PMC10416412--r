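# Minimal ctce3d pipeline configuration; unset fields fall back to
# default_config(). Run with:
#   inst/cli/ctce3d pipeline --config inst/extdata/example_config.yaml
seed: 1
gene: KRAS
output_dir: ctce3d_out
field:
  extent: [4000.0, 1500.0, 400.0]
  background: 0.02
  clones:
    - center: [1200.0, 700.0, 150.0]
      scale: [700.0, 450.0, 160.0]
      peak: 0.8
layout:
  n_blocks: 2
  rows: 6
  cols: 8
  circle_area: 25000.0
  pitch_xy: 250.0
  z_planes: [0.0, 100.0, 200.0, 300.0, 400.0]
trace:
  noise_sd: 2.5
dropout: 0.1
stats:
  level: 0.95
interpolation:
  method: linear
  resolution: [30, 20, 12]
render:
  isolevels: [0.4]
  colormap: Viridis
  format: png
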
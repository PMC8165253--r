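# Demo configuration: small wire phantom, end-to-end run.
# All physical quantities in SI units.
seed: 5
output_dir: runs/demo
stages: [simulate, characterize, reconstruct, analyze]
geometry:
  nx: 12
  ny: 12
  pitch: 2.0e-4      # 200 um step
  rep_rate: 10
sensor:
  bw3db: 2.3e+7      # 23 MHz design bandwidth
  nep: 65.8          # Pa over the full band
phantom:
  type: wire
  wire_diameter: 9.0e-6
  depths: [1.5e-3, 2.5e-3]
  y_length: 1.0e-3
  amplitude: 5.0e+5  # strong wire contrast: peak signals >> 65.8 Pa noise
simulate:
  fs: 1.25e+8
  n_samples: 320
  noise: true
grid:
  shape: [15, 9, 40]
  voxel: 5.0e-5
  origin: [-3.5e-4, -2.0e-4, 1.2e-3]
analysis:
  resolution: {}
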
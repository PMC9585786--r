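# Acquisition protocol presets for 7 T calf 23Na imaging.
# tr/te/ti in ms, nominal_resolution in mm, flip in degrees.
b0_map:
  tr: 139
  te: [0.60, 1.60]
  flip: 90
  matrix: 128
  nominal_resolution: 4.0
  n_projections: 4000
  pulse_duration: 1.0
b1_map:
  tr: 150
  te: [1.0]
  flip: 90
  matrix: 128
  nominal_resolution: 4.0
  n_projections: 4000
  pulse_duration: 2.0
t1_ir:
  tr: [253, 370]          # one TR per TI, linearly spaced across the range
  te: [0.80]
  ti: [3, 15, 30, 60, 120]
  flip: 90
  matrix: 128
  nominal_resolution: 6.5
  n_projections: 2600
  pulse_duration: 1.5
t2star:
  tr: 65
  te: [0.4, 0.6, 1.0, 2.0, 5.0, 10.0, 12.0, 14.0, 16.0, 18.0, 20.0, 22.0,
       24.0, 26.0, 29.0, 32.0, 36.0, 40.0, 45.0, 50.0]
  flip: 90
  matrix: 128
  nominal_resolution: 5.8
  n_projections: 9000
  pulse_duration: 0.68
sodium:
  tr: 100
  te: [0.55]
  flip: 90
  matrix: 128
  nominal_resolution: 2.5
  n_projections: 10000
  pulse_duration: 0.5
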
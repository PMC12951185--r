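# Default pipeline configuration. All values are SI unless noted.
head:
  brain_radius: 0.070
  outer_radius: 0.085
  conductivity: 0.33      # informational: the induced field is independent of it
  coil_center: [0.0, 0.0, 0.09]
  drive_frequency_hz: 3000
design:
  E_targ: 100             # V/m at the target depth (convention)
  alpha: 2                # peak-field cap ratio
  energy_budget_j: 200
  target_depth_m: 0.0131
support:
  shape: hat
  resolution: 0.007
winding:
  wire_width: 0.003
  wire_height: 0.003
  min_inductance_h: 8.8e-6
  min_spacing: 0.0022     # admissible same-layer concentric spacing
  shell_samples: 46532    # field-matching shell sample count
  energy_penalty: 1.0e-5  # weight of W_coil in the level objective
  layers:
    figure8: 3
    biasing: 1
    cancellation: 1
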
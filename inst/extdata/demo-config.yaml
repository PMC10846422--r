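# Desk-scale run: 0.5 mm voxels, reduced balloon, standard protocol
seed: 1
phantom:
  grid_shape: [48, 48, 48]
  extent_cm: [2.4, 2.4, 2.4]
  balloon_axes_cm: [1.8, 1.4, 1.2]
  sphere_radius_mm: 2
  saline_gap_mm: 0.5
  margin_cm: 0.3
mcrt:
  n_packets: 20000
thermal:
  size_cm: 1.2
  n_voxels: 24
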
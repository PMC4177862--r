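# Small synthetic demonstration run: 6 subjects per group, coarse
# registration, completes in a few minutes on one CPU.
mode: synthetic
synthetic_spec: default
n_per_group: 6
anterior_direction: "+col"
rect_mode: axis_aligned
pixel_convention: pixel_extent
fractions: [0.33, 0.17, 0.17, 0.13, 0.20]
registration:
  schedule_px: [8, 4, 2]
  iterations: 100
  template_iterations: 3
sites: [site1]
out_dir: ccmorph_demo_out
seed: 20
write_fields: true
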
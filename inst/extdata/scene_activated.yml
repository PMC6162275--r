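# Example scene description: the activated (cAMP-bound) 2D-crystal imaged
# from the intracellular face. Read with read_scene().
lattice:
  preset: activated      # a = b = 11.6 nm, gamma = 90, two tetramers/cell
  extent: 6
footprint:
  face: intracellular    # CNBD lobes + gating-ring disk
tip:
  radius: 2.0            # nm, spherical apex
scan:
  pixel_size: 0.35       # nm/px
  pixel_noise_sd: 0.05   # nm
  line_offset_sd: 0.02   # nm
  frame_interval: 1.0    # s
  seed: 1
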
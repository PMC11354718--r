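# Default bench scene: glass dish with Tyrode buffer, submerged tuber slab,
# two stainless needle electrodes touching the slab top surface.
# Lengths in mm, conductivities in S/m.

[geometry]
dish_inner_diameter = 96
dish_height = 30
dish_wall_thickness = 2
slab_length = 40
slab_width = 40
slab_height = 20
slab_top_offset = 4
electrode_diameter = 0.63
electrode_length = 8
electrode_gap = 1.37
electrode_tip_contact = true

[materials.bath]
name = "tyrode"
conductivity = 1.8
relative_permittivity = 1

[materials.slab]
name = "tuber"
conductivity = 0.04
relative_permittivity = 1

[materials.electrode_a]
name = "electrode"
conductivity = 0.00174
relative_permittivity = 1

[materials.electrode_b]
name = "electrode"
conductivity = 0.00174
relative_permittivity = 1

[recipe]
amplitude = 300
phase_duration = 10
frequency = 10
pulse_count = 100
interphase_delay = 500
polarity = "biphasic"

[solver]
spacing = 0.1
tolerance = 1e-8
max_iterations = 20000
domain = "local"
lateral_half_extent = 8
slab_depth_extent = 8
bath_margin = 10
electrode_mode = "equipotential"
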
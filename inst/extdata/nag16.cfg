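# 16 mm OSU-NAG plaque: 8 seeds glued to the shell, forming two concentric
# squares (inner half-diagonal 3.0 mm; outer 5.5 mm, rotated 45 degrees).
# Seed-centre depth = 1.0 mm sclera + 0.4 mm seed radius.
type: nag16
diameter: 16
inner_half_diagonal: 3.0
outer_half_diagonal: 5.5
inner_phase: 0
seed_center_depth: 1.4
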
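# 16 mm COMS plaque: 13 seeds approximating three isocentric circles
# (1 central + inner ring of 4 + outer ring of 8), equal source strength.
# Transverse ring radii in mm; seed-centre depth measured from the inner
# sclera (1.0 mm sclera + 1.75 mm carrier seed-plane offset).
type: coms16
diameter: 16
ring_radii: 3.0 5.8
ring_counts: 4 8
ring_phases: 0 22.5
seed_center_depth: 2.75
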
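arteriole_diameter_mm: 0.50
arteriole_angle_deg: 90
iph_angles_deg: [210, 330]
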
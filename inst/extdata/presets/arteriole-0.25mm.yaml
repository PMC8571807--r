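arteriole_diameter_mm: 0.25
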
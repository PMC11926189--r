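# mRNA entry/exit marker offsets in the subtomogram-average frame
# (Angstrom, relative to the particle centre), for readMarkerConfig().
entry_offset: [55.0, 0.0, 0.0]
exit_offset: [-55.0, 0.0, 0.0]
trace_cutoff: 250      # polysome tracing, A (25 nm)
distance_cutoff: 500   # neighbour-distance analysis, A (50 nm)
map_direction: inverse
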
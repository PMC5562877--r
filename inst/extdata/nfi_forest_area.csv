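survey,forest_area_km2
6th,1749100
8th,2076500
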
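scale,total_km2
local,23749.63
state,45694.82
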
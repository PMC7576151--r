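habitat_class,layer,overlap_km2,printed_percent
local,slr_30cm,226.67,0.95
state,slr_305cm,4480.27,9.8
local,development,1616.86,6.81
state,development,7116.39,15.57
local,unprotected,3456.46,14.55
state,unprotected,24511.99,53.64
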
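scale,unit,km2,percent_of_scale_total
local,Big Bend,483.68,2
local,Central,10253.16,43
local,Eastern Panhandle,4415.34,19
local,North,870.15,4
local,South,3419.3,14
local,South Central,2603.18,11
local,Western Panhandle,1704.82,7
state,Big Bend,5126.14,11
state,Central,11010.42,24
state,Eastern Panhandle,10307.06,23
state,North,3903.69,9
state,South,5003.73,11
state,South Central,7985.75,17
state,Western Panhandle,2358.03,5
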
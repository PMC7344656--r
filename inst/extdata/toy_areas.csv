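area_id,x_km,y_km,adult_pop,irsd
A1,0,0,100,950
A2,10,0,200,1000
A3,40,0,300,1050
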
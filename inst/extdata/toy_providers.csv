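site_id,x_km,y_km,gp_count
S1,5,0,3
S2,35,0,2
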
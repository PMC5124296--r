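sample_id,class,dispersion,focus,wavenhl
control_min_1,control_min,0,-1,0
control_min_2,control_min,0,-1,0
control_max_1,control_max,5500,1,120000
control_max_2,control_max,5500,1,120000
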
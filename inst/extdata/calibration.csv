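parameter,value
slope,10.655
intercept,-0.0076
r_squared,0.99869
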
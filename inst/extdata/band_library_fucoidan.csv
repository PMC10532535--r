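# phycospec diagnostic band library: fucoidan, version 1.0
code,center,window_lo,window_hi,types,shoulder_expected,specificity
S=O,1220,1212,1228,fucoidan,FALSE,shared
O=S=O,1020,1012,1028,fucoidan,FALSE,shared
C-O-S,820,812,828,fucoidan,FALSE,shared
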
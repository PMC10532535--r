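# phycospec diagnostic band library: alginate, version 1.0
code,center,window_lo,window_hi,types,shoulder_expected,specificity
C-C/C=O,1600,1592,1608,alginate,FALSE,shared
C-OH,1410,1402,1418,alginate,FALSE,shared
GulA-1081,1081,1073,1089,alginate,FALSE,shared
O=S=O,1026,1018,1034,alginate,FALSE,shared
GulA-797,797,789,805,alginate,FALSE,shared
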
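# phycospec diagnostic band library: carrageenan, version 1.0
# windows chosen to cover reported apex positions of the iota/kappa standards
code,center,window_lo,window_hi,types,shoulder_expected,specificity
S=O,1240,1210,1270,iota|kappa|nu,FALSE,shared
DA*,1070,1050,1080,iota|kappa,TRUE,specific
G/D,972.5,966,979,iota|kappa|nu,FALSE,shared
DA,930,917,938,iota|kappa,FALSE,specific
DA2S*,905,888,913,iota,TRUE,specific
G/D6S*,867,859,878,nu,TRUE,specific
G4S,845,837,853,iota|kappa|nu,FALSE,shared
G/D2S,827.5,821,834,nu,FALSE,specific
G/D6S,817.5,811,824,nu,FALSE,specific
DA2S,805,797,813,iota,FALSE,specific
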
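building_type,compound,n,mean,sd,median
dwelling,formaldehyde,383,131,90,100
office,formaldehyde,406,85,56,74
dwelling,benzene,379,17,16,11
office,benzene,375,30,34,16
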
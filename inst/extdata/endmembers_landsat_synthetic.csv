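"endmember","band","reflectance"
"soil","blue",0.11
"soil","green",0.15
"soil","red",0.21
"soil","nir",0.3
"soil","swir1",0.4
"soil","swir2",0.35
"vegetation","blue",0.03
"vegetation","green",0.06
"vegetation","red",0.04
"vegetation","nir",0.45
"vegetation","swir1",0.22
"vegetation","swir2",0.09
"shade","blue",0.02
"shade","green",0.03
"shade","red",0.02
"shade","nir",0.03
"shade","swir1",0.02
"shade","swir2",0.01
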
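"class","tp","fn","fp","tn"
"N",9189,107,121,3909
"V",684,35,239,12368
"R",1287,3,31,12005
"L",1419,30,85,11792
"noise",271,301,0,12754
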
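"class","tp","fn","fp","tn"
"N",9189,107,25,3433
"V",684,35,72,11998
"R",1287,3,20,11444
"L",1419,30,58,11247
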
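"record","N","V","R","L","A"
105,401,15,0,0,0
106,312,2,0,0,0
108,275,5,0,0,2
109,0,7,0,411,2
111,0,0,0,343,0
112,428,0,0,0,0
113,288,0,0,0,1
115,316,0,0,0,0
116,384,11,0,0,0
118,0,3,347,0,11
119,245,80,0,0,0
121,301,0,0,0,0
122,421,0,0,0,0
201,441,0,0,0,0
202,261,4,0,0,0
205,449,3,0,0,0
207,0,0,0,349,0
208,242,245,0,0,0
209,365,0,0,0,178
212,140,0,319,0,0
213,501,48,0,0,0
214,0,33,0,346,1
219,364,15,0,0,0
220,352,0,0,0,1
221,327,80,0,0,0
222,366,0,0,0,0
223,390,16,0,0,0
228,312,18,0,0,0
230,392,0,0,0,0
231,13,1,287,0,0
232,0,0,330,0,0
233,372,138,0,0,4
234,462,0,0,0,0
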
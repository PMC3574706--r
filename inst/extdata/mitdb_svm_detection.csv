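"record","tp","fn","fp"
105,416,0,24
106,312,2,26
108,282,0,37
109,419,1,10
111,343,0,186
112,428,0,81
113,289,0,0
115,316,0,0
116,395,0,4
118,361,0,11
119,325,0,12
121,301,0,20
122,421,0,0
201,441,0,0
202,265,0,1
205,452,0,0
207,349,0,13
208,480,7,11
209,541,2,52
212,455,4,9
213,548,1,4
214,376,4,8
219,378,1,9
220,353,0,0
221,407,0,0
222,366,0,5
223,406,0,0
228,330,0,1
230,392,0,0
231,301,0,41
232,330,0,3
233,514,0,4
234,462,0,0
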
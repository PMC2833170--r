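year,identified,total
2000,4,14
2001,1,16
2002,1,9
2003,10,19
2004,8,15
2005,13,20
2006,30,52
2007,11,17
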
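line,c8,c9,c10,abnormal
DV1,16,77,36,5
HUB1,18,72,42,5
LS1,276,5,0,4
LS2,61,0,0,0
LS3,23,6,17,4
IBK2,44,1,0,5
field_lignano,120,1,0,1
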
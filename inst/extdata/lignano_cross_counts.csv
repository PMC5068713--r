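parent1,parent2,c8,c9,c10,n_crosses
9,8,15,10,0,5
9,9,8,54,25,7
9,10,0,16,10,5
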
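class,Normal,Stage 1,Stage 2,Stage 3
Normal,34,5,2,3
Stage 1,9,26,2,4
Stage 2,4,2,15,2
Stage 3,0,2,7,11
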
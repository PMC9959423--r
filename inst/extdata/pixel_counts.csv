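id,white_yellow,opaque,brown
F1_2,280326,22737,0
F3_1,200431,117650,5397
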
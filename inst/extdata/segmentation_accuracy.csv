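stage,n_images,acc_mask,acc3
Normal,44,91.97,91.57
Stage 1,41,93.71,79.55
Stage 2,23,89.52,67.74
Stage 3,20,92.93,66.08
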
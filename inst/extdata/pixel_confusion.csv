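class,white,yellow,opaque,brown,background
white,405,18,3,0,0
yellow,18,386,0,0,0
opaque,31,4,181,2,0
brown,4,3,0,96,0
background,1,8,0,2,174
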
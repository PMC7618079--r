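"","homA<1/2,homB<1/2","homA>=1/2,homB<1/2","homA<1/2,homB>=1/2","homA>=1/2,homB>=1/2"
"hetA<1/2,hetB<1/2",305,17,11,0
"hetA>=1/2,hetB<1/2",0,407,0,4
"hetA<1/2,hetB>=1/2",0,0,476,16
"hetA>=1/2,hetB>=1/2",4,105,128,1313
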
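variant,*1,*2,*3,*4
rs12475068,C,G,,
rs1000002,T,,C,
rs1000003,A,,,
rs1000004,G,,,
c.776G>C,G,,,C
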
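item,u1,u2,u3,u4,u5
u1,1,3,5,3,1
u2,0.33,1,1.67,1,0.33
u3,0.2,0.6,1,0.6,0.2
u4,0.33,1,1.67,1,0.33
u5,1,3,5,3,1
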
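criterion,indicator,Poor,Relatively Poor,General,Good,Very Good
u1,u11,0.57,0.36,0.07,0.00,0.01
u1,u12,0.01,0.20,0.29,0.33,0.18
u1,u13,0.02,0.05,0.07,0.49,0.37
u1,u14,0.15,0.11,0.38,0.24,0.12
u1,u15,0.06,0.20,0.32,0.26,0.16
u2,u21,0.16,0.18,0.34,0.21,0.11
u2,u22,0.10,0.26,0.41,0.13,0.10
u2,u23,0.06,0.28,0.36,0.18,0.13
u2,u24,0.12,0.33,0.31,0.17,0.08
u2,u25,0.22,0.32,0.38,0.08,0.00
u2,u26,0.20,0.17,0.19,0.26,0.18
u2,u27,0.24,0.49,0.23,0.04,0.00
u3,u31,0.12,0.14,0.39,0.23,0.13
u3,u32,0.13,0.11,0.37,0.27,0.13
u3,u33,0.26,0.18,0.32,0.13,0.11
u3,u34,0.17,0.29,0.36,0.09,0.09
u4,u41,0.06,0.42,0.34,0.12,0.06
u4,u42,0.11,0.38,0.28,0.13,0.11
u4,u43,0.24,0.26,0.24,0.18,0.08
u5,u51,0.08,0.39,0.28,0.15,0.11
u5,u52,0.35,0.27,0.21,0.13,0.04
u5,u53,0.04,0.41,0.36,0.11,0.08
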
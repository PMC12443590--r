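vessel,velocity,diameter
ICA_L,0.62,0.0048
ICA_R,0.58,0.0051
VA_L,0.38,0.0035
VA_R,0.41,0.0033
MCA_L,0.55,0.0030
MCA_R,0.53,0.0029
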
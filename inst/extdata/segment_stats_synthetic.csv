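label,mean_mm,sd_mm
T10,21.3,2.2
T11,20.6,2.1
T12,19.8,2.3
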
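"length","Rh"
1130.77,128.35
2261.54,218.71
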
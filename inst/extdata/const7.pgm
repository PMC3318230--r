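P2
# 4x4 constant test image
4 4
255
7 7 7 7
7 7 7 7
7 7 7 7
7 7 7 7
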
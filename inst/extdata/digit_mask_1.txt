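000000000000000000000000000000000
000000000000000000000000000000000
000000000000000000000000000000000
000000000000000000000000000000000
000000000000000000000000000000000
000000000000000000000000000000000
000000000000000000000000000000000
000000000000000000000000000000000
000000000000000000000000000000000
000000000000000000000000000000000
000000000000000000000000000000000
000001100000000000000000000000000
000011110000000000000000000000000
000000110000000000000000000000000
000000110000000000000000000000000
000000110000000000000000000000000
000000110000000000000000000000000
000000110000000000000000000000000
000000110000000000000000000000000
000000110000000000000000000000000
000000110000000000000000000000000
000011111000000000000000000000000
000000000000000000000000000000000
000000000000000000000000000000000
000000000000000000000000000000000
000000000000000000000000000000000
000000000000000000000000000000000
000000000000000000000000000000000
000000000000000000000000000000000
000000000000000000000000000000000
000000000000000000000000000000000
000000000000000000000000000000000
000000000000000000000000000000000
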
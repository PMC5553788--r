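R1
R3
R5
R7
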
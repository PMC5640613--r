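G0001
G0002
G0003
G0004
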
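11000000001111010010
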
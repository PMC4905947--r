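x = 3, y = 3, rule = B3/S23
bo$2bo$3o!
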
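CYP1A2: 0.8147
CYP2C9: 0.8018
CYP2D6: 0.8551
CYP2C19: 0.8054
CYP3A4: 0.6450
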
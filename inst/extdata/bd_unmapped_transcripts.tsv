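gene	analysis
LOC100131360	E
LOC728649	E
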
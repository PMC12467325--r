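visual,digital_LOW,digital_HIGH
LOW,63,0
HIGH,13,21
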
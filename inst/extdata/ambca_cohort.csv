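strain,females,males
C57BL/6J,174,195
FVB.CD1(ICR),69,69
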
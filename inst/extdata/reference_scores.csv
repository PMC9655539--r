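target,protocol,ligand,score_low,score_high,is_reference
AChE,rigid,safinamide,-13.05,-11.16,FALSE
AChE,rigid,benzamide,-12.13,-11.43,FALSE
AChE,rigid,donepezil,-14.71,-12.64,TRUE
AChE,flexible,safinamide,-7.35,-5.83,FALSE
AChE,flexible,benzamide,-7.84,-6.62,FALSE
AChE,flexible,donepezil,-8.52,-6.29,TRUE
HDAC2,rigid,safinamide,-11.72,-10.42,FALSE
HDAC2,rigid,benzamide,-13.01,-11.30,TRUE
HDAC2,rigid,donepezil,-13.24,-10.92,FALSE
HDAC2,flexible,safinamide,-7.17,-5.62,FALSE
HDAC2,flexible,benzamide,-7.68,-6.74,TRUE
HDAC2,flexible,donepezil,-8.51,-6.10,FALSE
MAOB,rigid,safinamide,-13.56,-12.45,TRUE
MAOB,rigid,benzamide,-7.84,-4.66,FALSE
MAOB,rigid,donepezil,-9.12,-5.28,FALSE
MAOB,flexible,safinamide,-8.34,-7.69,TRUE
MAOB,flexible,benzamide,-9.08,-8.17,FALSE
MAOB,flexible,donepezil,-9.96,-8.31,FALSE
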
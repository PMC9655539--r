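pattern_id	smarts	description
acyclic_imine	[CX3;!R;!$([CX3](=[NX2])[#7,#8,#16])](=[NX2;!R][#6])	acyclic Schiff base (imine C=N, hydrolytically labile); excludes amidines, guanidines, imidates and ring-embedded C=N
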
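pattern_id	smarts	description
rhodanine	O=C1CSC(=S)N1	rhodanine (2-thioxothiazolidin-4-one) core
ene_rhodanine	O=C1C(=[CX3])SC(=S)N1	5-alkylidene/arylidene rhodanine (Michael acceptor)
thiazolidinone_ene	O=C1C(=[CX3])SC(=[NX2])N1	2-imino-thiazolidinone with exocyclic alkene
para_quinone	O=C1C=CC(=O)C=C1	para-quinone (redox cycler)
ortho_quinone	O=C1C(=O)C=CC=C1	ortho-quinone (redox cycler)
catechol	[OX2H]c1ccccc1[OX2H]	catechol (metal chelation, oxidation)
hydroquinone	[OX2H]c1ccc([OX2H])cc1	hydroquinone (redox cycler)
hzone_phenol	[OX2H]c1ccccc1[CH]=[NX2][NX3]	2-hydroxyphenyl hydrazone
azo_aryl	c[NX2]=[NX2]c	aryl azo dye
mannich_phenol	[OX2H]c1ccccc1[CH2][NX3;!$(N=O)]	phenolic Mannich base
barbiturate_ene	O=C1NC(=O)NC(=O)C1=[CX3]	alkylidene barbiturate (Michael acceptor)
dienone	C(=O)(C=C)C=C	cross-conjugated dienone (double Michael acceptor)
nitroso	[#6][NX2]=[OX1]	C-nitroso
isothiazolone	O=C1C=CSN1	isothiazolone (thiol-reactive)
acyl_hydrazone_phenol	[OX2H]c1ccccc1C(=O)N[NX2]=[CX3]	salicyl acylhydrazone
beta_keto_enol	[OX2H][CX3]=[CX3][CX3]=[OX1]	enolized 1,3-dicarbonyl
maleimide_ene	O=C1C=CC(=O)N1	maleimide (thiol-reactive Michael acceptor)
styryl_nitro	[CX3H]=[CX3H]c1ccc([NX3](=O)=O)cc1	beta-nitrostyrene-adjacent styryl nitroarene
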
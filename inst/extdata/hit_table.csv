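rank,name,smiles,ki_ache_nM,ki_hdac2_nM,ki_maob_nM,product_reported_nM3
1,Specs AH-487/42478269,S(=O)(=O)(NCCc1ccccc1)c2ccc(cc2)CCC(=O)N3CC[NH+](CC3)CC,131.0,5.971,0.6379,497.4
2,Tripos 1503-03309,Clc1ncccc1OC[C@@H]2OCCN(C(=O)CSc3cc(OC)c(OC)cc3)C2,3.808,1615,1.784,10970
3,Chembridge 7905648,Clc1c(cc(OCC)c(OCC(=O)NCCc2ccccc2)c1)C[NH2+]CCO,4346,6.160,0.5084,13610
4,Tripos 1526-25537,S=C(N1CCN(c2c(OCC)cccc2)CC1)Nc3cc4OCOc4cc3,17.04,868.2,0.9270,13720
5,EMC Microcollections 010F0838,O=C(N[C@H](CCCC(C)C)C)[C@@H]1[C@@H](C(=O)NCc2c3c(ccc2)cccc3)C[NH2+]C1,337.9,3339,0.1196,135000
6,Akos LT-1164 X 260,O=C(OC)c1cc(cc(c1)C=2OC(=CC2)C[NH2+]CCC=3c4c(NC3)cccc4)C(=O)OC,59.21,937.0,3.000,166400
7,Chembridge 7928210,S(=O)(=O)(NCC(C)C)c1cc(c(OCC(=O)Nc2cc(ccc2)C(=O)C)cc1)C,109.6,11.56,309.0,391700
8,Comgenex CGX-3274395,O=C(NCc1cc2OCOc2cc1)c3cc(ccc3)CN4c5c(OCC4=O)cccc5,14.15,13.76,3658,712200
9,Chem T&I SHCLME-048161,Clc1c(NC(=O)CSC2=NN=C(N2C)[C@@H](Oc3ccccc3)C)cc([N+]([O-])=O)cc1,34.19,72.17,439.6,1085000
10,Chem T&I AMCLME-10390,O=C(Nc1c(OC)ccc(OC)c1)C[NH+]2CCN(c3c(OCC)cccc3)CC2,335.9,930.0,5.961,1862000
11,Chemdiv 4378-0361,Clc1ccc(cc1)CS(=O)(=O)C[C@@H](O)CSc2nc3c(cc2C#N)CCCC3,88.81,517.3,93.30,4287000
12,Tripos 1547-01361,O(Cc1ccccc1)C[C@@H](O)C[NH+]2CCN(c3c4c(nc(c3)C)cccc4)CC2,4785,201.3,9.489,9142000
13,Chem T&I AMCLME-01759,S1C(NC(=O)C[NH+]2CC[NH+](Cc3cc(OC)ccc3)CC2)=C(C#N)C4=C1CCCCC4,727.6,2412,5.263,9238000
14,Asinex ASN 04448308,CCN(CC)S(=O)(=O)c1ccc(cc1)S(=O)(=O)NCCc1ccc2OCOc2c1,2203,323.0,52.53,37370000
15,Princeton Biomolecular OSSK_456453,[O-]C(=O)C(CCCC)NC(=O)C(C)Oc1ccc2c(c1)OC(=O)C=1CCCC2=1,65.99,1545,420.6,42880000
16,Asinex BAS 07211091,O=S(=O)(NCc1ccccc1)c1ccc(cc1)OCC(=O)NCc1ccncc1,4794,6.599,2053,64960000
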
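OC(=O)C=Cc1ccc(O)c(O)c1	Caffeic acid	in
CC1(C)C2CCC1(C)C(=O)C2	Camphor	in
CC1=CCC(CC1)C(=C)C	D-Limonene	in
CC12CCC(CC1)C(C)(C)O2	Eucalyptol	in
COc1cc(CC=C)ccc1O	Eugenol	up
OC(=O)c1cc(O)c(O)c(O)c1	Gallic acid	up
CC(C)=CCCC(C)=CC=O	Geranial	up
CCCCCCCO	Heptanol	up
OCc1ccc(C=O)o1	Hydroxy Methyl Furfural	up
CC(C)CCOC(C)=O	Isoamyl acetate	up
CC1=C(O)C(=O)C=CO1	Maltol	up
CC(C)C1CCC(C)CC1O	Menthol	in
CC(C)=CCCC(C)=CC=O	Neral	up
OC(=O)C=Cc1ccc(O)cc1	P-Coumaric acid	in
CCCCCC(O)C(O)C=CC(O)CCCCCCCC(=O)O	Pinellic acid	in
COc1cc(C=CC(=O)O)cc(OC)c1O	Sinapic acid	up
C=Cc1ccccc1	Styrene	up
COc1cc(C(=O)O)cc(OC)c1O	Syringic acid	up
COc1cc(C=CC(=O)O)ccc1O	Trans Ferulic acid	up
COc1cc(C(=O)O)ccc1O	Vanillic acid	in
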
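##gff-version 3
Gm04	phytozome	gene	51036742	51037897	.	+	.	ID=Glyma.04g242300;description=Plantacyanin
Gm04	phytozome	gene	51047485	51048880	.	+	.	ID=Glyma.04g242400;description=Unknown
Gm04	phytozome	gene	51053346	51056055	.	-	.	ID=Glyma.04g242500;description=Flavin-binding monooxygenase family protein
Gm04	phytozome	gene	51061920	51064096	.	+	.	ID=Glyma.04g242600;description=Unknown
Gm04	phytozome	gene	51064744	51067380	.	-	.	ID=Glyma.04g242700;description=F-box/RNI-like superfamily protein
Gm04	phytozome	gene	51082744	51092913	.	-	.	ID=Glyma.04g242800;description=ACT domain repeat 3
Gm04	phytozome	gene	51103163	51108385	.	-	.	ID=Glyma.04g242900;description=Protein kinase superfamily protein
Gm04	phytozome	gene	51109534	51115501	.	-	.	ID=Glyma.04g243000;description=Thiamin diphosphate-binding fold (THDP-binding) superfamily protein
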
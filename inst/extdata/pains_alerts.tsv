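# Curated subset of the published PAINS (pan-assay interference)
# substructure families A/B/C, as SMARTS. Editable: one alert per line.
# This is a representative selection of the most frequently matched
# families, not the full published list of 480 patterns.
name	smarts
quinone_A	O=C1C=CC(=O)C=C1
quinone_methide	C=C1C=CC(=O)C=C1
catechol_A	c1cc(O)c(O)cc1
hydroquinone	Oc1ccc(O)cc1
rhodanine	S=C1NC(=O)CS1
ene_rhodanine	C=C1SC(=S)NC1=O
thiazolidinone_ene	C=C1SC(=O)NC1=O
alkylidene_barbiturate	C=C1C(=O)NC(=O)NC1=O
hydroxyphenyl_hydrazone	Oc1ccccc1C=NN
phenol_schiff_base	Oc1ccccc1C=N
azo_aromatic	c1ccccc1N=Nc1ccccc1
ene_five_het_A	C=C1C(=O)NN=C1
mannich_phenol	OC1=CC=CC=C1CN(C)C
beta_keto_anhydride	O=C(C=C)OC(=O)C=C
imine_one_A	C(=N)C(=O)c1ccccc1
acyl_hydrazone	C(=O)NN=C
isothiazolone	S1C=CC(=O)N1
curcumin_dienone	C(=O)C=Cc1ccccc1
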
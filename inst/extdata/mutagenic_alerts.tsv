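# Curated subset of published mutagenicity toxicophores (approved
# substructure alerts from the mutagenicity structure-alert literature),
# as SMARTS. Editable: one alert per line.
name	smarts
aromatic_nitro	[c][N+](=O)[O-]
aromatic_nitroso	[c][NX2]=[OX1]
aliphatic_nitroso	[C;!$(C=O)][NX2]=[OX1]
nitrosamine	N-N=O
azide	[N-]=[N+]=N
triazene	N=N-N
azo	[C,c]N=N[C,c]
epoxide	C1OC1
aziridine	C1NC1
beta_lactone	O=C1CCO1
aliphatic_halide_primary	[CH2][Cl,Br,I]
bay_region_pah	c1ccc2c(c1)ccc3c2ccc4c3cccc4
aromatic_amine	[cX3][NX3;H2]
aromatic_hydroxylamine	[c][NX3;H1][OX2H]
hydrazine	[NX3;H2][NX3;H1,H2]
sulfonate_ester	COS(=O)(=O)[C,c]
polycyclic_nitroarene	[c]1ccc2ccccc2c1[N+](=O)[O-]
michael_acceptor_aldehyde	C=CC=O
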
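# ESOL linear model for log10 aqueous solubility (mol/L):
# logS = 0.16 - 0.63*clogP - 0.0062*MW + 0.066*RB - 0.74*AP
# (Delaney's estimated-solubility regression; AP = aromatic heavy-atom
# proportion, RB = rotatable bonds, MW in Da.)
term	value
intercept	0.16
clogp	-0.63
mw	-0.0062
rotb	0.066
aromatic_fraction	-0.74
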
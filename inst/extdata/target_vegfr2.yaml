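# Type II key-interaction specification for the VEGFR2 kinase domain.
name: VEGFR2
key_residues:
  hinge:   {chain: A, resno: 919,  resid: CYS}
  dfg:     {chain: A, resno: 1046, resid: ASP}
  alpha_c: {chain: A, resno: 885,  resid: GLU}
back_pocket:
  # hydrophobic residues lining the allosteric back pocket; contacts are
  # counted against these (C-C <= contact_dist)
  resids: [LEU, ILE, VAL, PHE, MET, ALA, TRP, PRO, CYS]
contact_dist: 4.5
min_contacts: 3
hbond:
  d_max: 3.5
  angle_min: 120
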
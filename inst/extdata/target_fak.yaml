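# Type II key-interaction specification for the FAK kinase domain.
name: FAK
key_residues:
  hinge:   {chain: A, resno: 502, resid: CYS}
  dfg:     {chain: A, resno: 564, resid: ASP}
  alpha_c: {chain: A, resno: 471, resid: GLU}
back_pocket:
  resids: [LEU, ILE, VAL, PHE, MET, ALA, TRP, PRO, CYS]
contact_dist: 4.5
min_contacts: 3
hbond:
  d_max: 3.5
  angle_min: 120
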
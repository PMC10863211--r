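# Feature-perception rule dictionary. One enabled rule per line;
# params are semicolon-separated key=value pairs. Editing this file
# changes the feature chemistry without touching code.
#
# ACC  lone_pair_NO : N/O atoms with an available lone pair
#                     (amide N and pyrrole-type aromatic N-H excluded)
# DON  polar_H      : N-H / O-H heavy atoms (explicit or implicit H)
# ARO  ring_centroid: centroid of each aromatic ring
# HYD  apolar_group : centroid of contiguous apolar carbon groups of
#                     at least min_atoms atoms; halogens on those
#                     carbons are included in the centroid
# DON_PROJ projection: projected-donor placement distance (Angstrom)
kind	rule	params
ACC	lone_pair_NO
DON	polar_H
ARO	ring_centroid
HYD	apolar_group	min_atoms=3;halogens=TRUE
DON_PROJ	projection	distance=2.8
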
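# BOILED-Egg classification ellipses in the TPSA (x, A^2) x WLOGP (y)
# plane. Reconstruction of the published best-fit ellipses (the white
# region bounds high predicted gastrointestinal absorption, the yolk
# bounds likely blood-brain-barrier permeation). width/height are full
# axis lengths; angle in degrees, counter-clockwise.
region	cx	cy	width	height	angle
gi	71.051	2.292	142.081	8.740	-1.031325
bbb	38.117	3.481	82.061	5.557	-0.171887
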
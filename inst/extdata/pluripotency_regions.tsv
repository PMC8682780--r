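protein_id	source	signature	name	start	end
Oct4	Pfam	PF00157	POU_specific	131	205
Nanog	Pfam	PF00046	Homeobox	96	155
Sox2	Pfam	PF00505	HMG_box	43	111
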
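# conjscreen core-OS biosynthesis table (reconstruction of the
# published prototype structures; see package documentation).
# selector columns describe the parent residue a product attaches to:
# its monosaccharide, its own anomeric/attachment-position linkage,
# and its parent's monosaccharide (ROOT = the lipid anchor).
gene	action	res_id	mono	stereo	anomeric	child_pos	parent_pos	token	position	sel_mono	sel_anomeric	sel_parent_pos	sel_parent_mono	requires
gmhD	precursor													
waaE	precursor													
wecA	precursor													
wzx	precursor													
waaA	residue	KdoI	Kdo		a	2	6			lipA				
waaA	residue	KdoII	Kdo		a	2	4			Kdo			lipA	
waaC	residue	HepI	Hep	D-D	a	1	5			Kdo			lipA	gmhD,waaE
waaP	substituent							P	4	Hep			Kdo	
waaF	residue	HepII	Hep	L-D	a	1	3			Hep			Kdo	gmhD,waaE
waaY	substituent							P	6	Hep		3	Hep	waaP
waaQ	residue	HepIII	Hep	L-D	a	1	7			Hep		3	Hep	gmhD,waaE
waaG	residue	GlcI	Glc		a	1	3			Hep		3	Hep	
waaB	residue	Gal	Gal		a	1	6			Glc		3	Hep	
waaO	residue	GlcII	Glc		a	1	3			Glc		3	Hep	
waaJ	residue	GlcIII	Glc		a	1	2			Glc		3	Glc	
waaK	residue	GlcNAc	GlcNAc		a	1	2			Glc		2	Glc	
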
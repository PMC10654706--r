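residue_id	mono	stereo	anomeric	child_pos	parent_pos	parent_id	substituents	added_by
lipA	lipA		n/a			ROOT		constitutive
KdoI	Kdo		a	2	6	lipA		waaA
KdoII	Kdo		a	2	4	KdoI		waaA
HepI	Hep	D-D	a	1	5	KdoI	4P:waaP	waaC
HepII	Hep	L-D	a	1	3	HepI	6P:waaY	waaF
HepIII	Hep	L-D	a	1	7	HepII		waaQ
GlcI	Glc		a	1	3	HepII		waaG
GlcNAcB	GlcNAc		b	1	3	GlcI		wabA
GlcII	Glc		a	1	3	GlcI		waaO
GalI	Gal		a	1	3	GlcII		waaI
GlcNAc	GlcNAc		a	1	3	GalI		waaD
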
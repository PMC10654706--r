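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
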
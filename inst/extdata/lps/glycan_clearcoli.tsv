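residue_id	mono	stereo	anomeric	child_pos	parent_pos	parent_id	substituents	added_by
lipA	lipA		n/a			ROOT		constitutive
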
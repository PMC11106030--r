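dialect	molecule	pore	shift
f5c_resquiggle	RNA	r9.4.1	1
f5c_resquiggle	DNA	r9.4.1	2
f5c_resquiggle	DNA	r10.4.1	1
f5c_resquiggle	RNA	rna004	1
eventalign	RNA	r9.4.1	1
eventalign	DNA	r9.4.1	2
eventalign	DNA	r10.4.1	1
eventalign	RNA	rna004	1
move_table	DNA	r9.4.1	0
move_table	DNA	r10.4.1	0
move_table	RNA	r9.4.1	0
move_table	RNA	rna004	0
tombo_tsv	DNA	r9.4.1	0
tombo_tsv	RNA	r9.4.1	0
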
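effective_release	event_type	source_wbids	target_wbids	note
WS152	merge	WBGene00000001,WBGene00000002	WBGene00000002	R07E5.12 merged into R07E5.10
WS217	merge	WBGene00000003,WBGene00000004	WBGene00000004	C03B8.1 merged into C03B8.3
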
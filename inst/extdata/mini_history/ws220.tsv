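wbid	sequence_name	public_name	transcript_names	status
WBGene00000001	R07E5.12		R07E5.12	dead
WBGene00000002	R07E5.10		R07E5.10a,R07E5.10b	live
WBGene00000003	C03B8.1		C03B8.1	dead
WBGene00000004	C03B8.3		C03B8.3	live
WBGene00000005	F08G5.6	nlp-29	F08G5.6	live
WBGene00000006	Y41D4B.17	lys-7	Y41D4B.17	live
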
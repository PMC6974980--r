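name	recognition	cut_offset_top
XhoI	CTCGAG	1
BamHI	GGATCC	1
EcoRI	GAATTC	1
HindIII	AAGCTT	1
PflFI	GACNNNGTC	4
PvuI	CGATCG	4
XbaI	TCTAGA	1
SalI	GTCGAC	1
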
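locus	group	parent	count
AciG35	5n	DAM	4
AciG35	5n	SIRE	6
AciG35	7n	DAM	8
AciG35	7n	SIRE	6
Afu68	5n	DAM	5
Afu68	5n	SIRE	5
Afu68	7n	DAM	9
Afu68	7n	SIRE	5
AfuG54	5n	DAM	4
AfuG54	5n	SIRE	7
AfuG54	7n	DAM	7
AfuG54	7n	SIRE	7
AfuG135	5n	DAM	4
AfuG135	5n	SIRE	6
AfuG135	7n	DAM	8
AfuG135	7n	SIRE	6
Aox45	5n	DAM	5
Aox45	5n	SIRE	5
Aox45	7n	DAM	8
Aox45	7n	SIRE	5
Spl101	5n	DAM	4
Spl101	5n	SIRE	6
Spl101	7n	DAM	8
Spl101	7n	SIRE	6
Spl163	5n	DAM	5
Spl163	5n	SIRE	7
Spl163	7n	DAM	9
Spl163	7n	SIRE	7
Spl173	5n	DAM	4
Spl173	5n	SIRE	6
Spl173	7n	DAM	6
Spl173	7n	SIRE	6
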
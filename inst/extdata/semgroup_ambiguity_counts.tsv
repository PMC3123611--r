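group	description	distinct	ambiguous	mesh
ACTI	Activities & Behaviors	7652	236	12
ANAT	Anatomy	183049	1328	182
CHEM	Chemicals & Drugs	1043202	15015	503
CONC	Concepts & Ideas	49701	3482	197
DEVI	Devices	40454	548	25
DISO	Disorders	230779	4574	354
GENE	Genes & Molecular Sequences	183096	15724	302
GEOG	Geographic Areas	1835	445	190
LIVB	Living Beings	433254	2475	141
OBJC	Objects	11658	577	36
OCCU	Occupations	3559	240	16
ORGA	Organizations	3939	175	18
PHEN	Phenomena	9903	240	18
PHYS	Physiology	307357	4437	80
PROC	Procedures	327686	1760	155
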
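# Drought- and ripening-associated cis-regulatory elements (6-8-mers, IUPAC)
ACGTGKC	ABRE
CACGTG	G-box
RCCGAC	DRE-core
RCCGACA	DRE
RYCGAC	DRE-related
MACCGMCW	DRE-related
CATGTG	NACR
TTRCGT	NACR
TTACGTGT	NACR
GCCGCC	GCC-box
CCGTTA	MYB
TGTCGG	AuxRE
ACACTA	ZAT6
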
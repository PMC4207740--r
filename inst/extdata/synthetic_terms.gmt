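CIRCADIAN_RHYTHM	synthetic term: molecular clock components	CLOCK	ARNTL	NPAS2	PER1	PER2	CRY1	NR1D1	DBP	BHLHE41	BHLHE40
IMMEDIATE_EARLY_RESPONSE	synthetic term: activity-induced transcription	FOS	EGR1	JUNB	NR4A1	IER1	DUSP1	DUSP6	CREB1
NEUROPEPTIDE_SIGNALING	synthetic term: neuropeptide and GPCR signalling	PENK	TAC1	TACR1	DRD2	ADORA2A
MYELINATION	synthetic term: oligodendrocyte and myelin markers	ENPP2	PLP1	CLDN11	SOX10	MBP	MAG
MOOD_DISORDER_ASSOCIATED	synthetic term: mood/psychotic disorder associations	DRD2	ADORA2A	PER1	PER2	CRY1	BHLHE41	BHLHE40	PENK	FOS	ARNTL
MAPK_CASCADE	synthetic term: MAPK signalling and its negative regulators	MAPK1	MAPK3	DUSP1	DUSP6	RHOA	IER1
TRANSPORT_MISC	synthetic term: unrelated background set	TTR	RBP4	LPAR1	NR4A2	ANLN	HSPA1B
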
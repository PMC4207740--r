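from	to	type
CLOCK	ARNTL	binding
NPAS2	ARNTL	binding
ARNTL	PER1	transcription
ARNTL	PER2	transcription
ARNTL	CRY1	transcription
ARNTL	DBP	transcription
ARNTL	NR1D1	transcription
CLOCK	PER1	transcription
CLOCK	PER2	transcription
CLOCK	CRY1	transcription
NPAS2	PER1	transcription
NPAS2	CRY1	transcription
PER1	CRY1	binding
PER2	CRY1	binding
NR1D1	ARNTL	transcription
DBP	PER1	transcription
BHLHE41	CLOCK	repression
BHLHE41	ARNTL	repression
BHLHE41	PER1	regulation
BHLHE40	CLOCK	repression
BHLHE40	ARNTL	repression
BHLHE40	PER2	regulation
BHLHE41	BHLHE40	binding
CREB1	FOS	transcription
CREB1	EGR1	transcription
CREB1	JUNB	transcription
CREB1	NR4A1	transcription
CREB1	PENK	transcription
CREB1	PER1	transcription
FOS	JUNB	binding
FOS	EGR1	regulation
FOS	PENK	transcription
FOS	TAC1	transcription
JUNB	TAC1	transcription
MAPK1	FOS	phosphorylation
MAPK1	EGR1	phosphorylation
MAPK1	CREB1	phosphorylation
MAPK3	FOS	phosphorylation
MAPK3	CREB1	phosphorylation
DUSP1	MAPK1	dephosphorylation
DUSP1	MAPK3	dephosphorylation
DUSP6	MAPK1	dephosphorylation
DUSP6	MAPK3	dephosphorylation
DRD2	MAPK1	signaling
DRD2	CREB1	signaling
ADORA2A	CREB1	signaling
ADORA2A	DRD2	binding
PENK	DRD2	signaling
TAC1	TACR1	binding
IER1	MAPK1	regulation
HSPA1B	FOS	chaperone
HSPA1B	MAPK1	chaperone
NR4A1	NR4A2	binding
SOX10	PLP1	transcription
SOX10	CLDN11	transcription
SOX10	MBP	transcription
ENPP2	PLP1	coexpression
ENPP2	LPAR1	signaling
PLP1	CLDN11	coexpression
BHLHE41	CREB1	regulation
PER1	CREB1	regulation
ARNTL	NR4A1	transcription
TTR	RBP4	binding
ANLN	RHOA	binding
RHOA	MAPK1	signaling
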
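ligand	receptor	library	source	assays
GAS1	PTPRA	TM1	Screen	SPR, CSS
OMG	PTPRD	TM1	PHA	SPR
OMG	PTPRF	TM1	PHA	SPR
OMG	PTPRS	TM1	PHA	SPR
OMG	PTPRU	TM1	Screen	SPR
OSTN	PTPRU	TM1	Screen	SPR
MK	RNF167	TM1	Screen	SPR
PTN	RNF167	TM1	Screen	SPR
PTN	ROR1	TM1	Screen	SPR
PTN	MFRP	TM1	Screen	SPR
SMOC1	SMOC1	TM1	PHA	SPR
SMOC1	SMOC2	TM1	Screen	SPR
TAFA2	KIR3DL1	TM1	Screen	SPR, CSS
TAFA2	KIR3DL2	TM1	PHA	SPR, CSS
TAFA2	KIR3DL3	TM1	Screen	CSS
TAFA2	KIR2DL5A	TM1	PHA	CSS
TAFA2	RNF167	TM1	Screen	SPR
TAFA5	RNF167	TM1	Screen	SPR
LY6H	CD36	TM2+	Screen	CSS
NRN1	CD36	TM2+	Screen	CSS
SCRG1	CD36	TM2+	Screen	CSS
VWC2L	CD36	TM2+	Screen	CSS
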
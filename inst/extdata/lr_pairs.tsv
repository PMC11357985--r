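pair	ligand_genes	receptor_genes
EFNB2_EPHB1	EFNB2	EPHB1
EFNB2_EPHA4	EFNB2	EPHA4
EFNB2_EPHB4	EFNB2	EPHB4
EFNA5_EPHA4	EFNA5	EPHA4
EFNA5_EPHA3	EFNA5	EPHA3
EFNA1_EPHA4	EFNA1	EPHA4
EFNB1_EPHB6	EFNB1	EPHB6
VEGFA_FLT1	VEGFA	FLT1
VEGFA_KDR	VEGFA	KDR
VEGFA_NRP1	VEGFA	NRP1
VEGFA_FLT1_NRP1	VEGFA	FLT1+NRP1
VEGFB_FLT1	VEGFB	FLT1
VEGFB_NRP1	VEGFB	NRP1
DLL4_NOTCH1	DLL4	NOTCH1
DLL1_NOTCH1	DLL1	NOTCH1
JAG1_NOTCH1	JAG1	NOTCH1
JAG1_NOTCH2	JAG1	NOTCH2
IGF1_IGF1R	IGF1	IGF1R
IGF2_IGF1R	IGF2	IGF1R
PDGFB_PDGFRB	PDGFB	PDGFRB
PDGFA_PDGFRA	PDGFA	PDGFRA
PDGFC_PDGFRA	PDGFC	PDGFRA
PDGFD_PDGFRB	PDGFD	PDGFRB
FGF2_FGFR1	FGF2	FGFR1
FGF1_FGFR1	FGF1	FGFR1
HGF_MET	HGF	MET
EGF_EGFR	EGF	EGFR
HBEGF_EGFR	HBEGF	EGFR
NRG1_ERBB4	NRG1	ERBB4
NRG1_ERBB2_ERBB4	NRG1	ERBB2+ERBB4
TGFB1_TGFBR1_TGFBR2	TGFB1	TGFBR1+TGFBR2
TGFB2_TGFBR1_TGFBR2	TGFB2	TGFBR1+TGFBR2
BMP2_BMPR1A_BMPR2	BMP2	BMPR1A+BMPR2
BMP4_BMPR1A_BMPR2	BMP4	BMPR1A+BMPR2
ANGPT1_TEK	ANGPT1	TEK
ANGPT2_TEK	ANGPT2	TEK
DKK1_LRP6	DKK1	LRP6
WNT5A_FZD1	WNT5A	FZD1
CXCL12_CXCR4	CXCL12	CXCR4
CCL2_CCR2	CCL2	CCR2
IL6_IL6R	IL6	IL6R
TNF_TNFRSF1A	TNF	TNFRSF1A
NPPA_NPR1	NPPA	NPR1
NPPB_NPR1	NPPB	NPR1
BDNF_NTRK2	BDNF	NTRK2
NGF_NTRK1	NGF	NTRK1
SEMA3A_NRP1	SEMA3A	NRP1
SLIT2_ROBO1	SLIT2	ROBO1
NTN1_DCC	NTN1	DCC
APLN_APLNR	APLN	APLNR
EDN1_EDNRA	EDN1	EDNRA
AGT_AGTR1	AGT	AGTR1
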
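immune_enrichment_synthetic	synthetic stand-in immune marker list for IES scoring; replace with a published immune signature for real analyses	PTPRC	CD2	CD3D	CD3E	CD3G	CD8A	CD8B	GZMA	GZMB	GZMK	PRF1	NKG7	KLRB1	KLRD1	CCL5	CXCR3	IL2RB	CD247	LCK	ZAP70
stromal_enrichment_synthetic	synthetic stand-in stromal marker list for SES scoring; replace with a published stromal signature for real analyses	COL1A1	COL1A2	COL3A1	COL5A1	COL6A3	FAP	PDGFRA	PDGFRB	DCN	LUM	FBLN1	FBN1	THBS2	SPARC	MMP2	ACTA2	TAGLN	VIM	ZEB1	POSTN
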
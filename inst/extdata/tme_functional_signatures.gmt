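immunosuppression	TME functional orientation	CXCL12	TGFB1	TGFB3	LGALS1
t_cell_activation	TME functional orientation	CXCL9	CXCL10	CXCL16	IFNG	IL15
t_cell_survival	TME functional orientation	CD70	CD27
tregs	TME functional orientation	FOXP3	TNFRSF18
mhc_class_i	TME functional orientation	HLA-A	HLA-B	HLA-C	HLA-E	HLA-F	HLA-G	B2M
myeloid_chemotaxis	TME functional orientation	CCL2
tertiary_lymphoid_structures	TME functional orientation	CXCL13
immune_checkpoints	immune checkpoint genes	PDCD1	CD274	PDCD1LG2	HAVCR2	CTLA4	LAG3
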
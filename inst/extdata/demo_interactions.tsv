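ligand_genes	receptor_genes	ligand_cell_type	receptor_cell_type	annotation
CXCL9	CXCR3	Mal	TCD8	chemotaxis
CXCL10	CXCR3	Mal	TCD8	chemotaxis
CXCL11	CXCR3	CAF	TCD8	chemotaxis
CXCL12	CXCR4	Mal	TCD8	chemotaxis
CXCL16	CXCR6	CAF	TCD8	chemotaxis
CX3CL1	CX3CR1	Endo	TCD8	chemotaxis
CCL2	CCR2	Mal	Macrophage	chemotaxis
CCL3	CCR5	NK	skinDC	chemotaxis
CCL4	CCR5	NK	skinDC	chemotaxis
CCL5	CCR5	skinDC	TCD8	chemotaxis
CCL21	CCR7	Endo	TCD4	chemotaxis
XCL1	XCR1	NK	skinDC	chemotaxis
CD274	PDCD1	Mal	TCD8	checkpoint
PDCD1LG2	PDCD1	Mal	TCD8	checkpoint
CD80	CTLA4	skinDC	TCD4	checkpoint
CD86	CTLA4	skinDC	TCD4	checkpoint
LGALS9	HAVCR2	Mal	TCD8	checkpoint
HLA-E	KLRC1_KLRD1	Mal	NK	checkpoint
ICAM1	ITGAL_ITGB2	Endo	TCD8	adhesion
VCAM1	ITGA4_ITGB1	Endo	TCD8	adhesion
SELE	SELPLG	Endo	TCD8	adhesion
CDH5	CDH5	Endo	Endo	adhesion
IL15	IL2RB_IL2RG	skinDC	NK	cytokine
IL18	IL18R1	Macrophage	NK	cytokine
IL12A_IL12B	IL12RB1_IL12RB2	skinDC	NK	cytokine
TGFB1	TGFBR1_TGFBR2	CAF	TCD4	growth_factor
VEGFA	FLT1	Mal	Endo	growth_factor
ANGPT2	TEK	Endo	Endo	growth_factor
CSF1	CSF1R	Mal	Macrophage	growth_factor
FLT3LG	FLT3	Mal	pDC	growth_factor
KITLG	KIT	CAF	pDC	cytotoxicity
TNFSF10	TNFRSF10B	NK	Mal	cytotoxicity
FASLG	FAS	TCD8	Mal	cytotoxicity
GZMB	IGF2R	TCD8	Mal	cytokine
IFNG	IFNGR1_IFNGR2	TCD8	Mal	cytokine
TNF	TNFRSF1A	Macrophage	Endo	chemotaxis
IL10	IL10RA_IL10RB	Macrophage	TCD4	chemotaxis
CCL19	CCR7	Endo	TCD4	chemotaxis
CCL20	CCR6	Mal	TCD4	chemotaxis
CXCL13	CXCR5	Bcell	TCD4	chemotaxis
PF4	CXCR3	Mal	TCD8	growth_factor
CCL8	CCR2	Macrophage	Macrophage	growth_factor
CXCL14	CXCR4	CAF	TCD8	checkpoint
IL34	CSF1R	Mal	Macrophage	checkpoint
CSF2	CSF2RA_CSF2RB	TCD4	pDC	checkpoint
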
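protein_name	gene_symbol	p_value	q_value	log2_fc	status
CD166 antigen	ALCAM	5.90E-04	4.91E-02	-2.12	Downregulated
Caveolin-1	CAV1	2.98E-04	4.91E-02	-1.72	Downregulated
Vimentin	VIM	4.09E-04	4.91E-02	-1.61	Downregulated
Myosin heavy chain-9	MYH9	4.04E-04	4.91E-02	1.58	Upregulated
SH3 domain-binding glutamic acid-rich-like protein 3	SH3BGRL3	2.68E-04	4.91E-02	2.70	Upregulated
Eukaryotic translation initiation factor 4B	EIF4B	5.78E-04	4.91E-02	2.77	Upregulated
Calpastatin	CAST	3.55E-04	4.91E-02	3.09	Upregulated
Nucleolar RNA helicase 2	DDX21	4.16E-04	4.91E-02	3.20	Upregulated
Creatine kinase U-type	CKMT1A	3.36E-04	4.91E-02	3.46	Upregulated
Thioredoxin domain-containing protein 17	TXNDC17	4.92E-04	4.91E-02	1.69	RC-77 T/E only
Type I cytoskeletal keratin 19	KRT19	7.77E-04	5.40E-02	-2.49	Downregulated
Serotransferrin	TF	7.29E-04	5.40E-02	-2.30	Downregulated
Integrin alpha-6	ITGA6	1.44E-03	5.40E-02	-1.93	Downregulated
Laminin subunit gamma-2	LAMC2	9.86E-04	5.40E-02	-1.72	Downregulated
CD59 glycoprotein	CD59	9.15E-04	5.40E-02	-1.65	Downregulated
Squalene synthase	FDFT1	1.23E-03	5.40E-02	-1.31	Downregulated
Filamin-A	FLNA	1.06E-03	5.40E-02	1.21	Upregulated
Hydroxyacyl-coenzyme A dehydrogenase	HADH	1.61E-03	5.40E-02	1.22	Upregulated
X-ray repair cross-complementing protein 5	XRCC5	1.42E-03	5.40E-02	1.35	Upregulated
Prothymosin alpha	PTMA	1.49E-03	5.40E-02	1.65	Upregulated
Cytosolic acyl coenzyme A thioester hydrolase	ACOT7	1.37E-03	5.40E-02	1.74	Upregulated
High mobility group protein HMG-I/HMG-Y	HMGA1	1.58E-03	5.40E-02	1.79	Upregulated
Putative pre-mRNA-splicing factor ATP-dependent RNA helicase DHX15	DHX15	1.10E-03	5.40E-02	2.10	Upregulated
Scaffold attachment factor B1	SAFB	1.59E-03	5.40E-02	2.27	Upregulated
Nucleoprotein TPR	TPR	1.62E-03	5.40E-02	3.52	Upregulated
Hemoglobin subunit alpha	HBA1	1.80E-03	5.54E-02	-1.87	RC-77 N/E only
Protein PML	PML	1.77E-03	5.54E-02	1.69	RC-77 T/E only
Ribosome-binding protein 1	RRBP1	1.89E-03	5.63E-02	1.64	Upregulated
Adenosylhomocysteinase	AHCY	2.00E-03	5.75E-02	1.68	Upregulated
Gamma-interferon-inducible protein 16	IFI16	2.37E-03	6.59E-02	1.39	Upregulated
Phosphoenolpyruvate carboxykinase	PCK2	2.51E-03	6.75E-02	3.04	Upregulated
14-3-3 protein sigma	SFN	2.60E-03	6.76E-02	1.49	Upregulated
Lamin-B1	LMNB1	3.04E-03	7.26E-02	-0.87	Downregulated
Alpha-actinin-1	ACTN1	3.05E-03	7.26E-02	1.06	Upregulated
High mobility group protein HMGI-C	HMGA2	2.95E-03	7.26E-02	2.19	Upregulated
Voltage-dependent anion-selective channel protein 1	VDAC1	4.59E-03	7.67E-02	-1.00	Downregulated
Integrin beta-1	ITGB1	3.48E-03	7.67E-02	-0.92	Downregulated
Non-histone chromosomal protein HMG-17	HMGN2	4.22E-03	7.67E-02	1.34	Upregulated
PDZ and LIM domain protein 1	PDLIM1	4.40E-03	7.67E-02	1.61	Upregulated
T-complex protein 1 subunit epsilon	CCT5	4.72E-03	7.67E-02	1.66	Upregulated
Aminopeptidase N	ANPEP	5.25E-03	7.67E-02	-2.38	RC-77 N/E only
Prefoldin subunit 2	PFDN2	4.96E-03	7.67E-02	1.35	RC-77 T/E only
40S ribosomal protein S24	RPS24	4.96E-03	7.67E-02	1.35	RC-77 T/E only
Serine/arginine-rich splicing factor 1	SRSF1	4.96E-03	7.67E-02	1.35	RC-77 T/E only
S-formylglutathione hydrolase	ESD	5.05E-03	7.67E-02	1.42	RC-77 T/E only
RNA-binding protein EWS	EWSR1	5.15E-03	7.67E-02	1.47	RC-77 T/E only
Hepatoma-derived growth factor	HDGF	5.15E-03	7.67E-02	1.47	RC-77 T/E only
Non-histone chromosomal protein HMG-14	HMGN1	4.96E-03	7.67E-02	1.47	RC-77 T/E only
S-methyl-5'-thioadenosine phosphorylase	MTAP	4.96E-03	7.67E-02	1.47	RC-77 T/E only
Phosphoserine aminotransferase	PSAT1	5.15E-03	7.67E-02	1.53	RC-77 T/E only
60S ribosomal protein L10	RPL10	4.99E-03	7.67E-02	1.53	RC-77 T/E only
Proteasome activator complex subunit 3	PSME3	5.22E-03	7.67E-02	1.58	RC-77 T/E only
40S ribosomal protein S11	RPS11	4.99E-03	7.67E-02	1.64	RC-77 T/E only
tRNA-splicing ligase RtcB homolog	RTCB	5.25E-03	7.67E-02	1.64	RC-77 T/E only
Double-stranded RNA-specific adenosine deaminase	ADAR	5.25E-03	7.67E-02	1.92	RC-77 T/E only
Eukaryotic translation initiation factor 3 subunit I	EIF3I	5.22E-03	7.67E-02	1.96	RC-77 T/E only
60S ribosomal protein L35	RPL35	5.18E-03	7.67E-02	2.08	RC-77 T/E only
Cytochrome c oxidase subunit 5A	COX5A	5.74E-03	8.24E-02	-1.38	Downregulated
Beta-catenin	CTNNB1	5.93E-03	8.37E-02	1.40	Upregulated
Type II cytoskeletal keratin 8	KRT8	6.14E-03	8.52E-02	-1.79	Downregulated
CD44 antigen	CD44	6.44E-03	8.60E-02	-0.77	Downregulated
Plasminogen activator inhibitor 1 RNA-binding protein	SERBP1	6.51E-03	8.60E-02	1.58	Upregulated
60S ribosomal protein L6	RPL6	6.38E-03	8.60E-02	2.14	Upregulated
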
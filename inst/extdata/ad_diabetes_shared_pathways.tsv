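source	term	adjusted_p	associated_genes
KEGG	Adipocytokine signaling pathway	1.13778E-11	ADIPOQ, LEP, LEPR, NPY, PCK1, PPARA, PPARGC1A, SLC2A4, TNF
KEGG	Advanced glycation end products(AGE)-receptor of AGE(RAGE) signaling pathway in diabetes complications	7.53638E-12	BAX, BCL2, CASP3, IL-1B, IL-6, NOS3, PIK3R1, TGFB1, TNF, VEGFA
KEGG	AMP-activated protein kinase (AMPK) signaling pathway	1.11028E-12	ADIPOQ, IGF1, INSR, LEP, LEPR, PCK1, PIK3R1, PPARG, PPARGC1A, SIRT1, SLC2A4
KEGG	Amyotrophic lateral sclerosis (ALS)	5.99784E-06	BAX, BCL2, CASP3, CAT, TNF
KEGG	Apoptosis	1.78131E-06	BAX, BCL2, CASP3, FAS, NGF, PIK3R1, TNF
KEGG	Fluid shear stress and atherosclerosis	1.94221E-10	BCL2, CAV1, CYBA, HMOX1, IL-1B, NOS3, NQO1, PIK3R1, TNF, VEGFA
KEGG	FoxO signaling pathway	1.09653E-10	CAT, IGF1, IL-6, INSR, PCK1, PIK3R1, SIRT1, SLC2A4, SOD2, TGFB1
KEGG	Hypoxia-inducible factor 1(HIF-1) signaling pathway	2.35735E-08	BCL2, HMOX1, IGF1, IL-6, INSR, NOS3, PIK3R1, VEGFA
KEGG	Hypertrophic cardiomyopathy (HCM)	2.93532E-05	ACE, IGF1, IL-6, TGFB1, TNF
KEGG	Insulin resistance	6.54836E-10	IL-6, INSR, NOS3, PCK1, PIK3R1, PPARA, PPARGC1A, SLC2A4, TNF
KEGG	Longevity regulating pathway	2.31646E-12	ADIPOQ, BAX, CAT, IGF1, INSR, PIK3R1, PPARG, PPARGC1A, SIRT1, SOD2
KEGG	Non-alcoholic fatty liver disease (NAFLD)	7.09E-15	ADIPOQ, BAX, CASP3, FAS, IL1B, IL-6, INSR, LEP, LEPR, PIK3R1, PPARA, TGFB1, TNF
KEGG	p53 signaling pathway	1.3591E-05	BAX, BCL2, CASP3, FAS, IGF1
KEGG	TNF signaling pathway	6.98289E-06	CASP3, FAS, IL-1B, IL-6, PIK3R1, TNF
KEGG	Type II diabetes mellitus	2.81374E-06	ADIPOQ, INSR, PIK3R1, SLC2A4, TNF
Reactome	FOXO-mediated transcription	2.09583E-08	CAT, CAV1, NPY, PCK1, PPARGC1A, SIRT1, SOD2
Reactome	FOXO-mediated transcription of oxidative stress, metabolic and neuronal genes	4.15153E-07	CAT, NPY, PCK1, PPARGC1A, SOD2
Reactome	Interleukin 4(IL-4) and interleukin 13(IL-13) signaling	2.25725E-08	BCL2, HMOX1, IL-1B, IL-6, PIK3R1, TGFB1, TNF, VEGFA
Reactome	Transcriptional regulation of white adipocyte differentiation	6.99501E-11	ADIPOQ, LEP, PCK1, PPARA, PPARG, PPARGC1A, SLC2A4, TGFB1, TNF
Reactome	VEGFA-VEGF receptor 2(VEGFR2) pathway	9.37356E-06	CAV1, CYBA, NOS3, PIK3R1, VEGFA
WikiPathways	Adipogenesis	6.4079E-14	ADIPOQ, FAS, IGF1, IL-6, LEP, PCK1, PPARA, PPARG, PPARGC1A, SLC2A4, TGFB1, TNF
WikiPathways	AMPK signaling	8.09075E-07	ADIPOQ, INSR, LEP, LEPR, PIK3R1, SLC2A4
WikiPathways	ALS	1.34735E-06	BAX, BCL2, CASP3, CAT, TNF
WikiPathways	Apoptosis	1.32024E-07	BAX, BCL2, CASP3, FAS, IGF1, PIK3R1, TNF
WikiPathways	Folate metabolism	4.39784E-08	CAT, IL-1B, IL-6, INSR, MPO, SOD2, TNF
WikiPathways	Genes involved in male infertility	1.61695E-08	ABCB1, BCL2, CAT, FAS, INSR, NOS3, NQO1, SOD2, TNF
WikiPathways	Hepatitis B infection	2.8804E-07	BAX, BCL2, CASP3, FAS, IL-6, PIK3R1, TGFB1, TNF
WikiPathways	Leptin signaling pathway	1.30077E-06	BAX, IL-1B, LEP, LEPR, NOS3, PIK3R1
WikiPathways	NAFLD	1.7843E-14	ADIPOQ, BAX, CASP3, FAS, IL-1B, IL-6, INSR, LEP, LEPR, PIK3R1, PPARA, TGFB1, TNF
WikiPathways	Photodynamic therapy-induced activator protein 1(AP-1) survival signaling	4.08953E-06	BAX, BCL2, FAS, IL-6, TNF
WikiPathways	T-Cell antigen receptor (TCR) signaling pathway	2.47953E-05	FAS, IL-1B, IL-6, PIK3R1, TGFB1
WikiPathways	TNF alpha signaling pathway	1.45408E-05	BAX, CASP3, CYBA, IL-6, TNF
WikiPathways	Transcription factor regulation in adipogenesis	3.4134E-14	ADIPOQ, IL-6, INSR, LEP, PPARG, PPARGC1A, SLC2A4, TNF
WikiPathways	Vitamin B12 metabolism	2.19331E-07	IL-1B, IL-6, INSR, MPO, SOD2, TNF
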
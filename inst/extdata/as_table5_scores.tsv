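# Strong-band ANN scores for the 22 multi-motive candidate proteins, as printed.
# Sparse: only strong-band (score >= 63) rows are printed per protein.
uniprot_id	gene_name	protein_name	motive_id	is_effector	ann_score
P08123	COL1A2	Collagen alpha-2(I) chain	myocardial_fibrosis	TRUE	92.52
P08123	COL1A2	Collagen alpha-2(I) chain	inflammation	FALSE	90.86
P08123	COL1A2	Collagen alpha-2(I) chain	endothelial_dysfunction	TRUE	87.5
P08123	COL1A2	Collagen alpha-2(I) chain	das_general	TRUE	69.82
P35625	TIMP3	Metalloproteinase inhibitor 3	endothelial_dysfunction	TRUE	91.85
P35625	TIMP3	Metalloproteinase inhibitor 3	das_general	TRUE	82.53
P35625	TIMP3	Metalloproteinase inhibitor 3	calcification	FALSE	69.2
P35625	TIMP3	Metalloproteinase inhibitor 3	raa_system	FALSE	63.61
P02461	COL3A1	Collagen alpha-1(III) chain	myocardial_fibrosis	TRUE	91.69
P02461	COL3A1	Collagen alpha-1(III) chain	endothelial_dysfunction	TRUE	87.29
P02461	COL3A1	Collagen alpha-1(III) chain	das_general	TRUE	76.47
P01033	TIMP1	Metalloproteinase inhibitor 1	endothelial_dysfunction	TRUE	91.45
P01033	TIMP1	Metalloproteinase inhibitor 1	das_general	TRUE	84.6
P01033	TIMP1	Metalloproteinase inhibitor 1	calcification	FALSE	68.8
P05231	IL6	Interleukin-6	myocardial_fibrosis	TRUE	90.45
P05231	IL6	Interleukin-6	calcification	TRUE	88.05
P05231	IL6	Interleukin-6	inflammation	TRUE	87.64
P05231	IL6	Interleukin-6	das_general	TRUE	73.24
P01042	KNG1	Kininogen-1	das_general	TRUE	90.45
P01042	KNG1	Kininogen-1	inflammation	TRUE	87.34
P01042	KNG1	Kininogen-1	raa_system	FALSE	70.1
P01042	KNG1	Kininogen-1	calcification	FALSE	63.4
P07339	CTSD	Cathepsin D	das_general	TRUE	87.0
P07339	CTSD	Cathepsin D	endothelial_dysfunction	TRUE	84.46
P07339	CTSD	Cathepsin D	hypertrophy	FALSE	71.66
P21810	BGN	Biglycan	inflammation	TRUE	86.97
P21810	BGN	Biglycan	calcification	FALSE	84.26
P21810	BGN	Biglycan	myocardial_fibrosis	FALSE	83.08
P21810	BGN	Biglycan	das_general	TRUE	80.74
P21810	BGN	Biglycan	endothelial_dysfunction	FALSE	78.98
P21810	BGN	Biglycan	lipoprotein_accumulation	FALSE	70.5
P14625	HSP90B1	Endoplasmin	inflammation	FALSE	86.48
P14625	HSP90B1	Endoplasmin	endothelial_dysfunction	FALSE	74.62
P14625	HSP90B1	Endoplasmin	das_general	FALSE	70.58
P14625	HSP90B1	Endoplasmin	lipoprotein_accumulation	FALSE	65.44
P01019	AGT	Angiotensinogen	das_general	TRUE	84.81
P01019	AGT	Angiotensinogen	myocardial_fibrosis	TRUE	82.54
P01019	AGT	Angiotensinogen	hypertrophy	TRUE	78.6
P01019	AGT	Angiotensinogen	raa_system	TRUE	65.54
P08253	MMP2	72 kDa type IV collagenase	calcification	TRUE	84.4
P08253	MMP2	72 kDa type IV collagenase	endothelial_dysfunction	TRUE	75.4
P08253	MMP2	72 kDa type IV collagenase	myocardial_fibrosis	TRUE	74.1
P08253	MMP2	72 kDa type IV collagenase	das_general	TRUE	73.98
P08253	MMP2	72 kDa type IV collagenase	hypertrophy	FALSE	71.88
P08253	MMP2	72 kDa type IV collagenase	oxidative_stress	FALSE	64.52
P02766	TTR	Transthyretin	oxidative_stress	FALSE	79.18
P02766	TTR	Transthyretin	inflammation	FALSE	74.11
P02766	TTR	Transthyretin	das_general	FALSE	71.21
P00441	SOD1	Superoxide dismutase [Cu-Zn]	inflammation	FALSE	78.56
P00441	SOD1	Superoxide dismutase [Cu-Zn]	das_general	TRUE	74.41
P00441	SOD1	Superoxide dismutase [Cu-Zn]	oxidative_stress	TRUE	69.12
P10909	CLU	Clusterin	inflammation	FALSE	76.5
P10909	CLU	Clusterin	endothelial_dysfunction	FALSE	67.68
P10909	CLU	Clusterin	lipoprotein_accumulation	FALSE	64.01
P07996	THBS1	Thrombospondin-1	endothelial_dysfunction	FALSE	76.17
P07996	THBS1	Thrombospondin-1	myocardial_fibrosis	FALSE	71.7
P07996	THBS1	Thrombospondin-1	raa_system	FALSE	63.52
P02768	ALB	Serum albumin	inflammation	FALSE	76.03
P02768	ALB	Serum albumin	endothelial_dysfunction	FALSE	75.65
P02768	ALB	Serum albumin	hypertrophy	FALSE	68.55
P02768	ALB	Serum albumin	lipoprotein_accumulation	FALSE	68.34
Q00653	NFKB2	Nuclear factor NF-kappa-B p100 subunit	inflammation	TRUE	75.62
Q00653	NFKB2	Nuclear factor NF-kappa-B p100 subunit	calcification	TRUE	74.83
Q00653	NFKB2	Nuclear factor NF-kappa-B p100 subunit	das_general	TRUE	72.15
P04114	APOB	Apolipoprotein B-100	endothelial_dysfunction	FALSE	75.04
P04114	APOB	Apolipoprotein B-100	inflammation	FALSE	74.02
P04114	APOB	Apolipoprotein B-100	das_general	TRUE	71.61
P04114	APOB	Apolipoprotein B-100	lipoprotein_accumulation	TRUE	64.6
P02647	APOA1	Apolipoprotein A-I	das_general	TRUE	74.73
P02647	APOA1	Apolipoprotein A-I	endothelial_dysfunction	FALSE	72.41
P02647	APOA1	Apolipoprotein A-I	lipoprotein_accumulation	TRUE	64.68
P07585	DCN	Decorin	calcification	FALSE	74.42
P07585	DCN	Decorin	endothelial_dysfunction	FALSE	73.11
P07585	DCN	Decorin	hypertrophy	FALSE	71.71
P07585	DCN	Decorin	myocardial_fibrosis	FALSE	68.53
Q92743	HTRA1	Serine protease HTRA1	myocardial_fibrosis	FALSE	72.82
Q92743	HTRA1	Serine protease HTRA1	endothelial_dysfunction	FALSE	72.73
Q92743	HTRA1	Serine protease HTRA1	das_general	FALSE	70.23
P01023	A2M	Alpha-2-macroglobulin	oxidative_stress	FALSE	72.55
P01023	A2M	Alpha-2-macroglobulin	myocardial_fibrosis	FALSE	70.52
P01023	A2M	Alpha-2-macroglobulin	inflammation	FALSE	68.56
P01023	A2M	Alpha-2-macroglobulin	endothelial_dysfunction	FALSE	68.3
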
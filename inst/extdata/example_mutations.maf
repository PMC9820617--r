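#version 2.4
Hugo_Symbol	Variant_Classification	HGVSp_Short	Tumor_Sample_Barcode
IDH1	Missense_Mutation	p.R132H	TCGA-EX-0004-01A
TP53	Missense_Mutation	p.R273H	TCGA-EX-0004-01A
IDH2	Missense_Mutation	p.R172K	TCGA-EX-0005-01A
TP53	Nonsense_Mutation	p.R306*	TCGA-EX-0007-01A
EGFR	Missense_Mutation	p.A289V	TCGA-EX-0008-01A
H3F3A	Missense_Mutation	p.K28M	TCGA-EX-0012-01A
TP53	Missense_Mutation	p.R175H	TCGA-EX-0010-01A
ATRX	Frame_Shift_Del	p.E1287fs	TCGA-EX-0005-01A
IDH1	Missense_Mutation	p.V71I	TCGA-EX-0009-01A
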
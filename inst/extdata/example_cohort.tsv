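case_id	histology	hist_grade	idh_status	codel_1p19q	atrx	tertp	egfr_amp	gain7_loss10	cdkn2ab_hd	h3_status	age_at_diagnosis	os_time	os_event
TCGA-EX-0001	oligodendroglioma	II	mutant	yes	wildtype	mutant	no	no	no	wildtype	41	88.4	0
TCGA-EX-0002	oligodendroglioma	III	mutant	yes	wildtype	mutant	no	no	no	wildtype	47	61.0	1
TCGA-EX-0003	oligoastrocytoma	III	mutant	yes	wildtype	wildtype	no	no	no	wildtype	39	72.9	0
TCGA-EX-0004	astrocytoma	II	mutant	no	mutant	wildtype	no	no	no	wildtype	33	94.1	0
TCGA-EX-0005	astrocytoma	III	mutant	no	mutant	wildtype	no	no	no	wildtype	36	50.6	1
TCGA-EX-0006	astrocytoma	II	mutant	no	mutant	wildtype	no	no	yes	wildtype	40	30.2	1
TCGA-EX-0007	astrocytoma	II	wildtype	no	wildtype	mutant	no	no	no	wildtype	58	16.8	1
TCGA-EX-0008	glioblastoma	IV	wildtype	no	wildtype	mutant	yes	yes	yes	wildtype	63	11.5	1
TCGA-EX-0009	glioblastoma	IV	wildtype	no	wildtype	wildtype	no	yes	no	wildtype	66	14.3	1
TCGA-EX-0010	glioblastoma	IV	unknown	unknown	unknown	unknown	unknown	unknown	unknown	wildtype	59	9.9	1
TCGA-EX-0011	astrocytoma	III	wildtype	no	wildtype	unknown	unknown	unknown	unknown	unknown	52	20.7	0
TCGA-EX-0012	glioblastoma	IV	wildtype	no	wildtype	wildtype	no	no	no	K27M	28	10.1	1
TCGA-EX-0013	unknown	unknown	unknown	unknown	unknown	unknown	unknown	unknown	unknown	unknown	55	NA	NA
TCGA-EX-0014	oligoastrocytoma	II	mutant	no	mutant	wildtype	no	no	no	wildtype	37	NA	NA
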
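pathway	gene	arr
synthetic_ecm_depth1	FREM2	1
synthetic_ecm_depth1	ITGB1	1
synthetic_ecm_depth1	FN1	1
synthetic_ecm_depth1	SPRY1	-0.5
synthetic_ecm_depth1	DUSP6	-1
synthetic_ecm_depth2	FREM2	1
synthetic_ecm_depth2	ITGB1	1
synthetic_ecm_depth2	FN1	1
synthetic_ecm_depth2	ITGA5	0.5
synthetic_ecm_depth2	COL4A1	0.5
synthetic_ecm_depth2	NID1	0
synthetic_ecm_depth2	SPRY1	-0.5
synthetic_ecm_depth2	DUSP6	-1
synthetic_ecm_depth2	SPRED1	-1
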
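subtype	gene
Proneural	SIG_PN_01
Proneural	SIG_PN_02
Proneural	SIG_PN_03
Proneural	SIG_PN_04
Proneural	SIG_PN_05
Classical	SIG_CL_01
Classical	SIG_CL_02
Classical	SIG_CL_03
Classical	SIG_CL_04
Classical	SIG_CL_05
Mesenchymal	SIG_MES_01
Mesenchymal	SIG_MES_02
Mesenchymal	SIG_MES_03
Mesenchymal	SIG_MES_04
Mesenchymal	SIG_MES_05
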
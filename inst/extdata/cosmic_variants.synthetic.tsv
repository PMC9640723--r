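key	gene	label
chr14:105246551:T:C	AKT1	AKT1_E17K_like
chr3:178952085:A:G	PIK3CA	PIK3CA_H1047R_like
chr12:25398284:C:T	KRAS	KRAS_G12_like
chr7:55259515:T:G	EGFR	EGFR_L858R_like
chr17:37880220:T:C	ERBB2	ERBB2_V777_like
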
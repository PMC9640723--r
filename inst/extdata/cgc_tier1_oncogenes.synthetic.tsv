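gene	tier	oncogenic_effect
AKT1	1	missense
PIK3CA	1	missense
KRAS	1	missense
EGFR	1	missense
MYC	1	other
ERBB2	1	missense
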
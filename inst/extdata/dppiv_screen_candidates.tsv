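sequence	binding_pvalue	known_dppiv_inhibitor
PR	1.45e-4	FALSE
IP	1.98e-4	TRUE
LP	2.07e-4	TRUE
LPQ	4.91e-4	TRUE
FT	1.49e-3	FALSE
SIPR	1.77e-3	FALSE
GI	2.07e-3	TRUE
MI	2.12e-3	TRUE
SAPI	2.23e-3	FALSE
ML	2.25e-3	TRUE
GL	3.53e-3	TRUE
FVPH	3.56e-3	FALSE
VF	3.63e-3	TRUE
FV	3.63e-3	FALSE
AL	5.87e-3	TRUE
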
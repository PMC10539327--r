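# Printed fixed-effect coefficients of the experimental reciprocal-cross
# model: per-sex dispersers out of 100 on cross type (sire line first;
# reference "HmLf" = high-line sire x low-line dam), sex (reference female)
# and their interaction.  These are data, not code.
term	estimate
intercept	63.93
cross_HmHf	22.81
cross_LmHf	3.47
cross_LmLf	-21.16
sex_male	0.83
cross_HmHf:sex_male	3.75
cross_LmHf:sex_male	0.31
cross_LmLf:sex_male	2.50
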
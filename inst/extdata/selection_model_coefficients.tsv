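# Printed fixed-effect coefficients of the experimental selection-response
# model: mean dispersals per individual (0-3) on an orthogonal second-order
# polynomial of generation, selection regime (reference "high"), block (0/1)
# and the generation-by-regime interactions.  These are data, not code.
term	estimate
intercept	2.16
generation_linear	2.21
generation_quadratic	-0.75
regime_low	-1.10
block	-0.06
generation_linear:regime_low	-5.64
generation_quadratic:regime_low	6.26
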
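# Published Bland-Altman proportional-bias regression p-values (EBUS minus
# histology) for six airway parameters, with the reported systematic-bias
# verdicts, from an equine EBUS-histology comparison of 109 isolated bronchi.
parameter,slope_p,intercept_p,reported_bias
perimeter,0.0001,0.02,yes
diameter,0.04,0.03,yes
lumen_area,0.08,0.98,no
asm_l2_area,0.083,0.99,no
asm_l2_area_over_pi,0.02,0.78,yes
asm_l2_area_over_pi2,0.0001,0.006,yes
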
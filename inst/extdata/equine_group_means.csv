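# Published group-mean airway measurements (mean over horses) from an equine
# EBUS-histology study of airway smooth muscle remodeling; airways Pi < 26 mm.
# quantity units: mm unless noted; group is control or heaves.
quantity,control,heaves
histo_pi_mm,18.94,20.09
histo_ecm_thickness_mm,0.0833,0.1356
histo_asm_thickness_mm,0.0762,0.1254
ebus_pi_mm,16.19,19.86
ebus_l1_mm,0.11,0.127
ebus_l2_mm,0.177,0.269
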
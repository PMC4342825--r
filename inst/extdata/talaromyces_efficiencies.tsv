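assay_id	efficiency_percent
R1	95.1
R2	99.2
R3	100.7
R4	101.1
R5	103.6
R6	93.1
R7	102.5
R8	96.3
R9	98.5
R10	100.5
R11	98.4
R12	98.2
beta_tub	97.2
abf_B2	103.6
xynC	94.4
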
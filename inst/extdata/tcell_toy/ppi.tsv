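protein_a	protein_b	combined_score
PR01	PR02	900
PR01	PR03	850
PR02	PR03	800
PR01	PR04	700
PR04	PR05	650
PR01	PR07	600
PR07	PR08	500
PR02	PR05	300
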
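reaction_id	reactant_ids	product_ids
RHEA00001	CPD006	CPD007|CPD008
RHEA00002	CPD006|CPDX99	CPD007
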
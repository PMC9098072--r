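term_id	name	parent_ids
GO:0002376	immune system process	
GO:0002711	positive regulation of T cell mediated immunity	GO:0002376
GO:0019882	antigen processing and presentation	GO:0002376
GO:0050900	leukocyte migration	GO:0002376
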
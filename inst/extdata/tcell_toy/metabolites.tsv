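metabolite_id	name	class	superclass	is_biological	is_inorganic	protein_ids	compound_id
MB01	sphingoid base 1	Sphingoid bases	Organic nitrogen compounds	1	0	PR01|PR02|PR03|PR07	CPD001
MB02	sphingoid base 2	Sphingoid bases	Organic nitrogen compounds	1	0	PR01|PR02|PR03|PR07	CPD002
MB03	sphingoid base 3	Sphingoid bases	Organic nitrogen compounds	1	0	PR01|PR02|PR03|PR08	CPD003
MB04	keto sphingoid base	Oxo compounds	Organic oxygen compounds	1	0	PR01|PR02|PR03|PR08|PR09	CPD004
MB05	committed sphingoid base	Ceramides	Organic acids and derivatives	1	0	PR01|PR02|PR03	CPD005
MB06	purine nucleoside donor	Nucleosides	Nucleosides, nucleotides, and analogues	1	0	PR04|PR05|PR07	CPD006
MB07	purine nucleoside diphosphate	Nucleotides	Nucleosides, nucleotides, and analogues	1	0	PR04|PR05|PR08	CPD007
MB08	purine nucleoside triphosphate	Nucleotides	Nucleosides, nucleotides, and analogues	1	0	PR04|PR05|PR08	CPD008
MB09	orphan metabolite	Carboxylic acids	Organic acids and derivatives	1	0	PR09	CPD009
MB10	mineral salt	Alkali metal salts	Inorganic compounds	1	1	PR01	CPD010
MB11	synthetic drug	Benzene derivatives	Benzenoids	0	0	PR02	CPD011
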
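protein_id	name	process_ids
PR01	T cell activator kinase	GO:0002711
PR02	antigen receptor subunit alpha	GO:0002711|GO:0019882
PR03	costimulatory ligand	GO:0002711
PR04	peripheral adapter 1	GO:0002711
PR05	peripheral adapter 2	GO:0002711
PR06	orphan immunity factor	GO:0002711
PR07	antigen processing chaperone	GO:0019882
PR08	leukocyte migration GTPase	GO:0050900
PR09	housekeeping enzyme	
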
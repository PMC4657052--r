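protein_name	pdb_id	tp	tn	fp	fn
Granulocyte Colony-Stimulating Factor	1CD9	1	2	0	0
Alpha1-Antitrypsin	1HP7	5	3	0	1
Prion Protein	1B10	2	2	0	1
IgG1-Fc	1FC1	2	1	0	0
Stem Cell Factor	1EXZ	2	1	0	0
Coagulation Factor VIIa	1QFK	2	1	1	0
Growth Hormone	1HGU	1	2	0	0
Chorionic Somatomammotropin	1Z7C	2	1	1	1
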
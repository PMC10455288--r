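record_id	strain	taxon_label	locus	is_type_strain	source
a1_ITS	a1	SpeciesA	ITS	TRUE	synthetic
a2_ITS	a2	SpeciesA	ITS	FALSE	synthetic
a3_ITS	a3	SpeciesA	ITS	FALSE	synthetic
b1_ITS	b1	SpeciesB	ITS	TRUE	synthetic
b2_ITS	b2	SpeciesB	ITS	FALSE	synthetic
a1_LSU28S	a1	SpeciesA	LSU28S	TRUE	synthetic
a2_LSU28S	a2	SpeciesA	LSU28S	FALSE	synthetic
a3_LSU28S	a3	SpeciesA	LSU28S	FALSE	synthetic
b1_LSU28S	b1	SpeciesB	LSU28S	TRUE	synthetic
b2_LSU28S	b2	SpeciesB	LSU28S	FALSE	synthetic
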
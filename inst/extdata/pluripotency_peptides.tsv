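peptide_id	protein_id	start	end	enriched_fraction
Oct4_151_170	Oct4	151	170	crosslinked
Oct4_180_188	Oct4	180	188	crosslinked
Nanog_51_66	Nanog	51	66	crosslinked
Nanog_76_87	Nanog	76	87	crosslinked
Nanog_76_89	Nanog	76	89	crosslinked
Sox2_83_97	Sox2	83	97	crosslinked
Sox2_274_293	Sox2	274	293	crosslinked
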
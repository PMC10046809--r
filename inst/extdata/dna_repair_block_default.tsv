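gene	category
Apex1	base_excision
Apex2	base_excision
Atm	damage_signalling
Atr	damage_signalling
Blm	homologous_recombination
Brca1	homologous_recombination
Brca2	homologous_recombination
Chek1	damage_signalling
Chek2	damage_signalling
Ercc1	nucleotide_excision
Ercc2	nucleotide_excision
Ercc3	nucleotide_excision
Ercc4	nucleotide_excision
Ercc5	nucleotide_excision
Ercc6	nucleotide_excision
Ercc8	nucleotide_excision
Exo1	mismatch
Fen1	base_excision
Lig1	ligation
Lig3	ligation
Lig4	nonhomologous_end_joining
Mbd4	base_excision
Mgmt	direct_reversal
Mlh1	mismatch
Mlh3	mismatch
Msh2	mismatch
Msh3	mismatch
Msh6	mismatch
Mutyh	base_excision
Nbn	homologous_recombination
Neil1	base_excision
Neil2	base_excision
Neil3	base_excision
Nthl1	base_excision
Ogg1	base_excision
Parp1	damage_signalling
Parp2	damage_signalling
Pcna	replication
Pms2	mismatch
Pola1	replication
Polb	base_excision
Pold1	replication
Pole	replication
Prkdc	nonhomologous_end_joining
Rad50	homologous_recombination
Rad51	homologous_recombination
Rad52	homologous_recombination
Rad54l	homologous_recombination
Rev1	translesion_synthesis
Rev3l	translesion_synthesis
Rpa1	replication
Smug1	base_excision
Tdg	base_excision
Ung	base_excision
Wrn	homologous_recombination
Xpa	nucleotide_excision
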
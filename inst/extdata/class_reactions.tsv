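# Curated lipid-class reaction fixture: a reduced, hand-checked subset of
# common glycerophospholipid / glycerolipid class reactions with database
# and gene cross references. Multi-valued fields: substrates/products use
# '+', db_refs/gene_refs/organisms use ';'. Empty organisms = unrestricted.
reaction_id	category	substrates	products	db_refs	gene_refs	organisms
HGM_PS_PE	headgroup_modification	PS	PE	RHEA:20828	PISD
HGM_PE_PC	headgroup_modification	PE	PC	RHEA:32735	PEMT	HSA;MMU;RNO
HGM_PC_PS	headgroup_modification	PC	PS	REACTOME:R-HSA-1483101	PTDSS1	HSA;MMU;RNO
HGAR_DG_PA	headgroup_addition_removal	DG	PA	RHEA:10272	DGKA;DGKB
HGAR_PC_DG	headgroup_addition_removal	PC	DG	RHEA:10604	PLCB1;PLCG1
HGAR_PA_PI	headgroup_addition_removal	PA	PI	REACTOME:R-HSA-1483226	CDIPT	HSA;MMU;RNO
FAAR_LPC_PC	fa_addition_removal	LPC	PC	RHEA:12937	LPCAT1;LPCAT2
FAAR_LPE_PE	fa_addition_removal	LPE	PE	RHEA:32995	LPEAT1
FAAR_LPI_PI	fa_addition_removal	LPI	PI	RHEA:33195	MBOAT7
FAAR_LPA_PA	fa_addition_removal	LPA	PA	RHEA:19709	AGPAT1;AGPAT2
FAAR_MG_DG	fa_addition_removal	MG	DG	RHEA:38463	MOGAT1
FAAR_DG_TG	fa_addition_removal	DG	TG	RHEA:10868	DGAT1;DGAT2
MERGE_PA_PG_CL	lipid_merging	PA+PG	CL	RHEA:45588	CRLS1
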
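# Catalogue of the gene sets used by the published analysis: per-species
# cisplatin-associated sets from CTD, their pairwise/triple conserved
# overlaps, the MeSH cisplatin set, and the per-subtype up/down
# differential-expression sets derived from the Lehmann TNBC study.
# Only set ids and sizes are recoverable; memberships are not printed.
# Note: the narrative text gives the rat-mouse overlap as 151 genes while
# the catalogue row (GS357329) says 150; both values are recorded here and
# neither is resolved (nothing downstream depends on it).
gs_id	n_genes	species	kind	subtype	direction	description
GS125959	2386	human	species_chemical	NA	NA	Cisplatin interacting with Homo sapiens associated genes (MeSH:D002945) in CTD
GS257116	883	mouse	species_chemical	NA	NA	Cisplatin interacting with Mus musculus associated genes (MeSH:D002945) in CTD
GS263765	616	rat	species_chemical	NA	NA	Cisplatin interacting with Rattus norvegicus associated genes (MeSH:D002945) in CTD
GS357326	378	human	pairwise_overlap	NA	NA	Genes from CTD that interact with cisplatin and are conserved in human and mouse
GS357330	219	human	pairwise_overlap	NA	NA	Genes from CTD that interact with cisplatin and are conserved in human and rat
GS357329	150	human	pairwise_overlap	NA	NA	Genes from CTD that interact with cisplatin and are conserved in rat and mouse (narrative text: 151)
GS271882	96	human	triple_overlap	NA	NA	Genes from CTD that interact with cisplatin and are conserved in human, mouse and rat
GS237976	319	human	mesh	NA	NA	[MeSH] Cisplatin:D002945
GS271616	215	human	subtype_de	BL1	up	Genes upregulated in the BL1 subtype of triple negative breast cancer
GS271617	154	human	subtype_de	BL2	up	Genes upregulated in the BL2 subtype of triple negative breast cancer
GS271618	535	human	subtype_de	IM	up	Genes upregulated in the IM subtype of triple negative breast cancer
GS271619	247	human	subtype_de	M	up	Genes upregulated in the M subtype of triple negative breast cancer
GS271621	805	human	subtype_de	LAR	up	Genes upregulated in LAR subtype of triple negative breast cancer
GS271724	829	human	subtype_de	MSL	up	Genes upregulated in the MSL subtype of triple negative breast cancer
GS271627	251	human	subtype_de	BL1	down	Genes downregulated in the BL1 subtype of triple negative breast cancer
GS271636	127	human	subtype_de	BL2	down	Genes downregulated in the BL2 subtype of triple negative breast cancer
GS271640	302	human	subtype_de	IM	down	Genes downregulated in the IM subtype of triple negative breast cancer
GS271722	446	human	subtype_de	M	down	Genes downregulated in the M subtype of triple negative breast cancer
GS271729	382	human	subtype_de	LAR	down	Genes downregulated in the LAR subtype of triple negative breast cancer
GS271725	255	human	subtype_de	MSL	down	Genes downregulated in the MSL subtype of triple negative breast cancer
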
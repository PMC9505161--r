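species	lineage	type	n_sites	codon1	codon2	codon3	silent	nonsynonymous	tRNA	rRNA	intron	intergenic
Cycas_revoluta	Cycadales	C-to-U	152	23	89	11	13	110	0	0	7	22
Cycas_revoluta	Cycadales	G-to-A	6	1	1	0	0	2	0	2	1	1
Zamia_furfuracea	Cycadales	C-to-U	265	36	111	42	41	148	0	0	20	56
Zamia_furfuracea	Cycadales	G-to-A	10	3	3	0	0	6	0	2	1	1
Ginkgo_biloba	Ginkgoaceae	C-to-U	304	53	157	27	27	210	0	0	23	44
Ginkgo_biloba	Ginkgoaceae	G-to-A	3	0	0	0	0	0	0	2	0	1
Cedrus_deodara	Pinaceae	C-to-U	95	15	67	3	3	82	0	0	9	1
Cedrus_deodara	Pinaceae	G-to-A	1	0	0	0	0	0	0	1	0	0
Abies_firma	Pinaceae	C-to-U	77	10	51	5	5	61	0	1	8	2
Abies_firma	Pinaceae	G-to-A	4	0	0	1	1	0	0	1	1	1
Picea_smithiana	Pinaceae	C-to-U	161	23	84	12	12	107	0	1	14	27
Picea_smithiana	Pinaceae	G-to-A	4	1	0	2	2	1	0	1	0	0
Pinus_armandii	Pinaceae	C-to-U	49	7	28	5	6	34	0	0	4	5
Pinus_armandii	Pinaceae	G-to-A	5	0	1	0	0	1	0	0	0	4
Ephedra_przewalskii	Gnetales	C-to-U	1	0	1	0	0	1	0	0	0	0
Ephedra_przewalskii	Gnetales	G-to-A	2	0	0	1	1	0	0	0	0	1
Welwitschia_mirabilis	Gnetales	C-to-U	2	1	0	1	1	1	0	0	0	0
Welwitschia_mirabilis	Gnetales	G-to-A	4	1	0	1	1	1	0	2	0	0
Gnetum_montanum	Gnetales	C-to-U	3	0	3	0	0	3	0	0	0	0
Gnetum_montanum	Gnetales	G-to-A	4	0	0	0	0	0	0	2	1	1
Podocarpus_macrophyllus	ConiferII	C-to-U	20	2	17	0	0	19	0	0	0	1
Podocarpus_macrophyllus	ConiferII	G-to-A	4	0	0	1	1	0	0	0	1	2
Araucaria_cunninghamii	ConiferII	C-to-U	45	4	32	3	5	34	0	0	1	5
Araucaria_cunninghamii	ConiferII	G-to-A	1	0	0	0	0	0	0	1	0	0
Sciadopitys_verticillata	ConiferII	C-to-U	41	7	20	5	5	27	0	0	4	5
Sciadopitys_verticillata	ConiferII	G-to-A	5	2	0	0	0	2	0	1	0	2
Cephalotaxus_sinensis	ConiferII	C-to-U	40	6	25	1	1	31	0	1	3	4
Cephalotaxus_sinensis	ConiferII	G-to-A	6	0	0	1	0	1	0	1	0	4
Taxus_cuspidata	ConiferII	C-to-U	25	1	19	2	2	20	0	0	0	3
Taxus_cuspidata	ConiferII	G-to-A	2	0	1	0	0	1	0	1	0	0
Cunninghamia_lanceolata	ConiferII	C-to-U	18	3	14	0	0	17	0	0	1	0
Cunninghamia_lanceolata	ConiferII	G-to-A	2	0	0	0	0	0	0	1	1	0
Taiwania_cryptomerioides	ConiferII	C-to-U	18	2	14	1	1	16	0	0	0	1
Taiwania_cryptomerioides	ConiferII	G-to-A	2	0	0	0	0	0	1	1	0	0
Metasequoia_glyptostroboides	ConiferII	C-to-U	24	4	14	3	4	17	0	0	0	3
Metasequoia_glyptostroboides	ConiferII	G-to-A	4	0	0	1	1	0	0	1	1	1
Platycladus_orientalis	ConiferII	C-to-U	24	5	13	0	1	17	0	0	1	5
Platycladus_orientalis	ConiferII	G-to-A	2	1	0	0	0	1	0	1	0	0
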
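assembly_id	gene_id	start	end	strand	description	domain_assignment	is_focal	subfamily
1096520459783	1096694953057	1	900	+	RecA-superfamily homolog	unassigned	1	Unknown1
1096520459783	1096694953059	1001	1900	+	FKBP-type peptidyl-prolyl cis-trans isomerase	Archaea	0	Unknown1
1096528150039	1096695533559	1	900	+	RecA-superfamily homolog	unassigned	1	Unknown2
1096528150039	1096695533561	1001	1900	+	ATP-dependent helicase	Archaea	0	Unknown2
1096627014936	1096697847133	1	900	+	RecA-superfamily homolog	unassigned	1	Phage-SAR2
1096627014936	1096697847135	1001	1900	+	GDP-mannose 4,6-dehydratase	Bacteria	0	Phage-SAR2
1096627014936	1096697847149	2001	2900	+	methyltransferase FkbM	Bacteria	0	Phage-SAR2
1096627021375	1096698308433	1	900	+	RecA-superfamily homolog	unassigned	1	Unknown2
1096627021375	1096698308421	1001	1900	+	ATP-dependent RNA helicase	Archaea	0	Unknown2
1096627021375	1096698308423	2001	2900	+	replication factor A	Archaea	0	Unknown2
1096627021375	1096698308425	3001	3900	+	S-adenosylmethionine synthetase	Bacteria	0	Unknown2
1096627021375	1096698308427	4001	4900	+	cobalt-precorrin-6A synthase	Archaea	0	Unknown2
1096627021375	1096698308429	5001	5900	+	NADH ubiquinone dehydrogenase	Bacteria	0	Unknown2
1096627021375	1096698308431	6001	6900	+	CbiG protein	Bacteria	0	Unknown2
1096627021375	1096698308435	7001	7900	+	chaperone protein dnaJ	Eukaryota	0	Unknown2
1096627021375	1096698308443	8001	8900	+	ATP-binding protein of ABC transporter	Bacteria	0	Unknown2
1096627021375	1096698308445	9001	9900	+	small nuclear riboprotein protein snRNP	Archaea	0	Unknown2
1096627289467	1096683378299	1	900	+	RecA-superfamily homolog	unassigned	1	RecA-like SAR1
1096627289467	1096683378297	1001	1900	+	DNA polymerase III alpha subunit	Bacteria	0	RecA-like SAR1
1096627295379	1096699819041	1	900	+	RecA-superfamily homolog	unassigned	1	Unknown2
1096627295379	1096699819039	1001	1900	+	S-adenosylmethionine synthetase	Bacteria	0	Unknown2
1096627295379	1096699819043	2001	2900	+	replication factor A	Bacteria	0	Unknown2
1096627295379	1096699819047	3001	3900	+	snRNP Sm-like protein	Archaea	0	Unknown2
1096627374158	1096700853217	1	900	+	RecA-superfamily homolog	unassigned	1	Phage-SAR1
1096627374158	1096700853219	1001	1900	+	gp43	Viruses/Phages	0	Phage-SAR1
1096627382978	1096701673303	1	900	+	RecA-superfamily homolog	unassigned	1	Phage-SAR1
1096627382978	1096701673301	1001	1900	+	T4-like DNA polymerase	Viruses/Phages	0	Phage-SAR1
1096627382978	1096701673305	2001	2900	+	T4-like DNA primase-helicase	Viruses/Phages	0	Phage-SAR1
1096627390330	1096686533379	1	900	+	RecA-superfamily homolog	unassigned	1	Unknown2
1096627390330	1096686533339	1001	1900	+	ATP-dependent helicase	Archaea	0	Unknown2
1096627390330	1096686533341	2001	2900	+	deoxyribodipyrimidine photolyase-related	Bacteria	0	Unknown2
1096627390330	1096686533343	3001	3900	+	Glycyl-tRNA synthetase alpha2 dimer	Archaea	0	Unknown2
1096627390330	1096686533345	4001	4900	+	RNA-binding protein	Bacteria	0	Unknown2
1096627390330	1096686533347	5001	5900	+	cobyrinic acid a,c-diamide synthase	Archaea	0	Unknown2
1096627390330	1096686533349	6001	6900	+	sdoxyribodipyrimidine photolyase	Archaea	0	Unknown2
1096627390330	1096686533351	7001	7900	+	DNA primase small subunit	Archaea	0	Unknown2
1096627390330	1096686533353	8001	8900	+	cobalt-precorrin-6A synthase	Archaea	0	Unknown2
1096627390330	1096686533355	9001	9900	+	cobalamin biosynthesis CbiG	Bacteria	0	Unknown2
1096627390330	1096686533359	10001	10900	+	DNA primase large subunit	Archaea	0	Unknown2
1096627390330	1096686533361	11001	11900	+	aldo/keto reductase	Bacteria	0	Unknown2
1096627390330	1096686533365	12001	12900	+	AP endonuclease	Archaea	0	Unknown2
1096627390330	1096686533369	13001	13900	+	ATP-dependent helicase	Archaea	0	Unknown2
1096627390330	1096686533371	14001	14900	+	translation initiation factor 2 alpha subunit	Archaea	0	Unknown2
1096627390330	1096686533373	15001	15900	+	translation initiation factor 2 alpha subunit	Archaea	0	Unknown2
1096627390330	1096686533375	16001	16900	+	sirohydrochlorin cobaltochelatase CbiXL	Bacteria	0	Unknown2
1096627390330	1096686533377	17001	17900	+	glutamate racemase	Bacteria	0	Unknown2
1096627390330	1096686533383	18001	18900	+	glycosyl transferase	Eukaryota	0	Unknown2
1096627390330	1096686533387	19001	19900	+	deoxyribodipyrimidine photolyase	Bacteria	0	Unknown2
1096627390330	1096686533389	20001	20900	+	AP endonuclease	Archaea	0	Unknown2
1096627390330	1096686533393	21001	21900	+	cbiC protein	Archaea	0	Unknown2
1096627390330	1096686533399	22001	22900	+	deoxyribodipyrimidine photolyase	Bacteria	0	Unknown2
1096627390330	1096686533405	23001	23900	+	cob(I)alamin adenosyltransferase	Bacteria	0	Unknown2
1096627390330	1096686533407	24001	24900	+	Phosphohydrolase	Bacteria	0	Unknown2
1096627390330	1096686533409	25001	25900	+	glycyl-tRNA synthetase	Archaea	0	Unknown2
1096627390330	1096686533415	26001	26900	+	30S ribosomal protein S6	Archaea	0	Unknown2
1096627390330	1096686533421	27001	27900	+	nuclease	Archaea	0	Unknown2
1096627390330	1096686533423	28001	28900	+	phosphohydrolase	Bacteria	0	Unknown2
1096627390330	1096686533427	29001	29900	+	cobalt-precorrin-3 methylase	Archaea	0	Unknown2
1096627390330	1096686533429	30001	30900	+	universal stress family protein	Bacteria	0	Unknown2
1096627390330	1096686533473	31001	31900	+	aryl-alcohol dehydrogenases related oxidoreductases	Eukaryota	0	Unknown2
1096627390330	1096686533505	32001	32900	+	snRNP Sm-like protein Chain A	Eukaryota	0	Unknown2
1096627520210	1096665977449	1	900	+	RecA-superfamily homolog	unassigned	1	Unknown1
1096627520210	1096665977451	1001	1900	+	single-stranded DNA binding protein	Viruses/Phages	0	Unknown1
1096627650434	1096689280551	1	900	+	RecA-superfamily homolog	unassigned	1	Unknown2
1096627650434	1096689280549	1001	1900	+	S-adenosylmethionine synthetase	Bacteria	0	Unknown2
1096628394294	1096682182125	1	900	+	RecA-superfamily homolog	unassigned	1	Unknown1
1096628394294	1096682182127	1001	1900	+	DNA polymerase I	Bacteria	0	Unknown1
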
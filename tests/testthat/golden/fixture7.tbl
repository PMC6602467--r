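>Feature fixture
181	1080	gene
			gene	psbA
181	1080	CDS
			gene	psbA
			product	photosystem II protein D1
			codon_start	1
2014	1265	gene
			gene	matK
2014	1265	CDS
			gene	matK
			product	maturase K
			codon_start	1
2191	3695	gene
			gene	atpF
2191	2601	CDS
3252	3695
			gene	atpF
			product	ATP synthase CF0 B subunit
			codon_start	1
3998	5345	gene
			gene	petB
3998	4003	CDS
4704	5345
			gene	petB
			product	cytochrome b6
			codon_start	1
5516	6678	gene
			gene	petD
5516	5523	CDS
6204	6678
			gene	petD
			product	cytochrome b6/f complex subunit IV
			codon_start	1
7836	6829	gene
			gene	rpl16
7836	7828	CDS
7227	6829
			gene	rpl16
			product	ribosomal protein L16
			codon_start	1
8511	9209	gene
			gene	psbD
8511	9209	CDS
			gene	psbD
			product	photosystem II protein D2
			codon_start	1
9584	9186	gene
			gene	psbN
9584	9186	CDS
			gene	psbN
			product	photosystem II protein N
			codon_start	1
9695	10405	gene
			gene	rps2
9695	10405	CDS
			gene	rps2
			product	ribosomal protein S2
			codon_start	1
10548	10621	gene
			gene	trnH-GUG
10548	10621	tRNA
			gene	trnH-GUG
			product	tRNA-trnH-GUG
10755	10682	gene
			gene	trnQ-UUG
10755	10682	tRNA
			gene	trnQ-UUG
			product	tRNA-trnQ-UUG
10816	10889	gene
			gene	trnS-GCU
10816	10889	tRNA
			gene	trnS-GCU
			product	tRNA-trnS-GCU
11023	10950	gene
			gene	trnT-GGU
11023	10950	tRNA
			gene	trnT-GGU
			product	tRNA-trnT-GGU
18121	18820	gene
			gene	rrn16
18121	18820	rRNA
			gene	rrn16
			product	rrn16 ribosomal RNA
18891	19790	gene
			gene	rrn23
18891	19790	rRNA
			gene	rrn23
			product	rrn23 ribosomal RNA
19861	19955	gene
			gene	rrn4.5
19861	19955	rRNA
			gene	rrn4.5
			product	rrn4.5 ribosomal RNA
20026	20135	gene
			gene	rrn5
20026	20135	rRNA
			gene	rrn5
			product	rrn5 ribosomal RNA
20206	20457	gene
			gene	trnI-GAU
20206	20242	tRNA
20423	20457
			gene	trnI-GAU
			product	tRNA-trnI-GAU
20538	20770	gene
			gene	trnA-UGC
20538	20575	tRNA
20736	20770
			gene	trnA-UGC
			product	tRNA-trnA-UGC
24151	25644	gene
			gene	ndhB
24151	25644	CDS
			gene	ndhB
			product	NADH-plastoquinone oxidoreductase subunit 2
			codon_start	1
26501	25902	gene
			gene	ndhF
26501	25902	CDS
			gene	ndhF
			product	NADH-plastoquinone oxidoreductase subunit 5
			codon_start	1
33880	33181	gene
			gene	rrn16
33880	33181	rRNA
			gene	rrn16
			product	rrn16 ribosomal RNA
33110	32211	gene
			gene	rrn23
33110	32211	rRNA
			gene	rrn23
			product	rrn23 ribosomal RNA
32140	32046	gene
			gene	rrn4.5
32140	32046	rRNA
			gene	rrn4.5
			product	rrn4.5 ribosomal RNA
31975	31866	gene
			gene	rrn5
31975	31866	rRNA
			gene	rrn5
			product	rrn5 ribosomal RNA
31795	31544	gene
			gene	trnI-GAU
31795	31759	tRNA
31578	31544
			gene	trnI-GAU
			product	tRNA-trnI-GAU
31463	31231	gene
			gene	trnA-UGC
31463	31426	tRNA
31265	31231
			gene	trnA-UGC
			product	tRNA-trnA-UGC
8130	8017	gene
20951	21182
21483	21508
			gene	rps12
8130	8017	CDS
20951	21182
21483	21508
			gene	rps12
			product	ribosomal protein S12
			exception	trans-splicing
			codon_start	1
8130	8017	gene
31050	30819
30518	30493
			gene	rps12
8130	8017	CDS
31050	30819
30518	30493
			gene	rps12
			product	ribosomal protein S12
			exception	trans-splicing
			codon_start	1
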
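##fileformat=VCFv4.2
##source=hand-constructed QC fixture (synthetic)
##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">
##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Length of structural variant (negative for deletions)">
##INFO=<ID=END,Number=1,Type=Integer,Description="End position (1-based inclusive)">
##ALT=<ID=DEL,Description="Deletion">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	s01	s02	s03	s04	s05	s06	s07	s08	s09	s10
chr1	1000	long1	N	<DEL>	.	PASS	SVTYPE=DEL;SVLEN=-10000001;END=10001000	GT	0/0	0/0	0/0	0/1	0/1	0/0	0/1	0/0	1/1	1/1
chr1	20000	long2	N	<DEL>	.	PASS	SVTYPE=DEL;SVLEN=-15000000;END=15019999	GT	0/0	0/1	0/0	0/0	0/1	0/0	0/0	1/1	0/1	0/0
chr1	30000	allhet	N	<DEL>	.	PASS	SVTYPE=DEL;SVLEN=-2000;END=31999	GT	0/1	0/1	0/1	0/1	0/1	0/1	0/1	0/1	0/1	0/1
chr1	40000	miss1	N	<DEL>	.	PASS	SVTYPE=DEL;SVLEN=-3000;END=42999	GT	0/0	0/0	./.	0/1	0/0	./.	0/1	0/0	1/1	./.
chr1	50000	miss2	N	<DEL>	.	PASS	SVTYPE=DEL;SVLEN=-1500;END=51499	GT	./.	0/0	0/1	./.	0/0	1/1	./.	0/1	0/0	./.
chr1	60000	mono1	N	<DEL>	.	PASS	SVTYPE=DEL;SVLEN=-2500;END=62499	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
chr1	70000	mono2	N	<DEL>	.	PASS	SVTYPE=DEL;SVLEN=-1200;END=71199	GT	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
chr1	100000	clean1	N	<DEL>	.	PASS	SVTYPE=DEL;SVLEN=-2000;END=101999	GT	0/0	0/0	0/1	0/0	0/1	0/0	0/1	0/0	1/1	1/1
chr1	120000	clean2	N	<DEL>	.	PASS	SVTYPE=DEL;SVLEN=-4000;END=123999	GT	0/0	0/1	0/0	0/0	0/1	0/0	0/0	1/1	0/1	0/0
chr1	140000	clean3	N	<DEL>	.	PASS	SVTYPE=DEL;SVLEN=-2500;END=142499	GT	0/0	0/1	./.	0/0	0/1	0/0	./.	0/1	0/0	1/1
chr1	160000	clean4	N	<DEL>	.	PASS	SVTYPE=DEL;SVLEN=-3500;END=163499	GT	0/0	0/0	0/1	0/0	0/0	0/0	0/1	0/0	0/0	1/1
chr1	180000	clean5	N	<DEL>	.	PASS	SVTYPE=DEL;SVLEN=-1000;END=180999	GT	0/0	0/1	0/1	1/1	0/1	0/0	0/1	1/1	0/1	1/1
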
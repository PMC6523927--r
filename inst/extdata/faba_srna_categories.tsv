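type	library	count	percent
Total	HC-4	47942551	100
Intergenic	HC-4	9985569	20.83
Mature (miRNA)	HC-4	3224519	6.73
Rfam other sncRNA	HC-4	73325	0.15
snRNA	HC-4	1405	0
unmap	HC-4	11040957	23.03
rRNA	HC-4	1773606	3.7
Hairpin	HC-4	38	0
snoRNA	HC-4	30566	0.06
Precursor	HC-4	27019	0.06
Repeat	HC-4	21771765	45.41
tRNA	HC-4	13782	0.03
Total	HSA	40682196	100
Intergenic	HSA	10292988	25.3
Mature (miRNA)	HSA	1653404	4.06
Rfam other sncRNA	HSA	94167	0.23
snRNA	HSA	4831	0.01
unmap	HSA	13725210	33.74
rRNA	HSA	1100198	2.7
Hairpin	HSA	9	0
snoRNA	HSA	14138	0.03
Precursor	HSA	11116	0.03
Repeat	HSA	13683732	33.64
tRNA	HSA	102403	0.25
Total	IC-1	43865674	100
Intergenic	IC-1	9475423	21.6
Mature (miRNA)	IC-1	6841472	15.6
Rfam other sncRNA	IC-1	24135	0.06
snRNA	IC-1	2381	0.01
unmap	IC-1	21005681	47.89
rRNA	IC-1	244021	0.56
Hairpin	IC-1	80	0
snoRNA	IC-1	9971	0.02
Precursor	IC-1	24531	0.06
Repeat	IC-1	6237390	14.22
tRNA	IC-1	589	0
Total	IS-4	41563472	100
Intergenic	IS-4	8197558	19.72
Mature (miRNA)	IS-4	5633410	13.55
Rfam other sncRNA	IS-4	35172	0.08
snRNA	IS-4	959	0
unmap	IS-4	20270917	48.77
rRNA	IS-4	358242	0.86
Hairpin	IS-4	147	0
snoRNA	IS-4	6058	0.01
Precursor	IS-4	40935	0.1
Repeat	IS-4	7018371	16.89
tRNA	IS-4	1703	0
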
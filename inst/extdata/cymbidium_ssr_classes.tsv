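unit_length	canonical_class	n
1	A/T	53
2	AC/GT	2
2	AG/CT	13
2	AT/AT	9
3	AAC/GTT	1
3	AAG/CTT	19
3	AAT/ATT	1
3	ACT/AGT	3
3	AGC/CTG	2
3	AGG/CCT	1
3	ATC/ATG	2
4	AAAC/GTTT	1
4	AAAG/CTTT	24
4	AACT/AGTT	1
4	AAGC/CTTG	1
4	AAGG/CCTT	1
4	AAGT/ACTT	1
4	AATG/ATTC	4
4	ACAG/CTGT	1
4	ACAT/ATGT	1
4	ACCG/CGGT	1
4	ACGG/CCGT	1
4	ACGT/ACGT	1
4	ACTC/AGTG	2
4	ACTG/AGTC	4
4	AGAT/ATCT	4
4	AGCC/CTGG	1
4	AGCG/CGCT	1
4	AGCT/AGCT	1
4	ATCC/ATGG	1
4	CCGG/CCGG	1
5	AGAGG/CCTCT	2
5	ATATC/ATATG	1
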
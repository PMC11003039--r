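ref_codon	edited_codon	n_sites
CAC	TAC	10
CAT	TAT	18
CGC	TGC	11
CGT	TGT	31
ACA	ATA	5
ACG	ATG	7
ACT	ATT	5
CGG	TGG	32
TCA	TTA	76
TCC	TTC	37
TCG	TTG	41
TCT	TTT	55
CGA	TGA	2
CCA	TCA	8
CCC	TCC	14
CCG	TCG	7
CCT	TCT	20
CCA	CTA	48
CCC	CTC	10
CCC	TTC	6
CCG	CTG	26
CCT	CTT	26
CCT	TTT	12
CTC	TTC	5
CTT	TTT	9
GCA	GTA	1
GCC	GTC	1
GCG	GTG	4
GCT	GTT	3
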
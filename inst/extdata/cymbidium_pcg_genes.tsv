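group	gene	length_bp	start_codon	stop_codon	n_aa	copies
ATP synthase	atp1	1530	ATG	TGA	510	1
ATP synthase	atp4	579	ATG	TGA	193	1
ATP synthase	atp6	969	ATG	TAG	323	1
ATP synthase	atp8	480	ATG	TAA	160	1
ATP synthase	atp9	225	ATG	CGA(TGA)	75	1
Cytochrome c biogenesis	ccmB	621	ATG	TGA	207	1
Cytochrome c biogenesis	ccmC	723	ATG	TAG	241	1
Cytochrome c biogenesis	ccmFc	1317	ATG	CGA(TGA)	439	1
Cytochrome c biogenesis	ccmFn	1707	ATG	TGA	569	1
Ubiquinol cytochrome c reductase	cob	1182	ATG	TGA	394	1
Cytochrome c oxidase	cox1	1584	ATG	TAA	528	1
Cytochrome c oxidase	cox2	801	ATG	TAG	267	1
Cytochrome c oxidase	cox3	798	ATG	TGA	266	1
Maturases	matR	1899	ATG	TAG	633	1
Transport membrane protein	mttB	351	ATG	TAG	117	1
NADH dehydrogenase	nad1	978	ACG(ATG)	TAA	326	3
NADH dehydrogenase	nad2	1509	ATG	TGA	503	2
NADH dehydrogenase	nad3	357	ATG	TAG	119	1
NADH dehydrogenase	nad4	1488	ATG	TGA	496	1
NADH dehydrogenase	nad4L	303	ATG	TAA	101	1
NADH dehydrogenase	nad5	2016	ATG	TAA	672	3
NADH dehydrogenase	nad6	747	ATG	TAG	249	1
NADH dehydrogenase	nad7	1185	ATG	TAG	395	1
NADH dehydrogenase	nad9	573	ATG	TAA	191	1
Ribosomal proteins (LSU)	rpl16	348	ATG	TAA	116	1
Ribosomal proteins (LSU)	rpl5	546	ATG	TAA	182	1
Ribosomal proteins (SSU)	rps12	378	ATG	TGA	126	1
Ribosomal proteins (SSU)	rps13	351	ATG	TGA	117	1
Ribosomal proteins (SSU)	rps14	303	ATG	TAG	101	1
Ribosomal proteins (SSU)	rps7	447	ATG	TAA	149	1
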